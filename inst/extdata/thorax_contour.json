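{"x":[1,0.992115,0.968583,0.929776,0.876307,0.809017,0.728969,0.637424,0.535827,0.425779,0.309017,0.187381,0.062791,-0.062791,-0.187381,-0.309017,-0.425779,-0.535827,-0.637424,-0.728969,-0.809017,-0.876307,-0.929776,-0.968583,-0.992115,-1,-0.992115,-0.968583,-0.929776,-0.876307,-0.809017,-0.728969,-0.637424,-0.535827,-0.425779,-0.309017,-0.187381,-0.062791,0.062791,0.187381,0.309017,0.425779,0.535827,0.637424,0.728969,0.809017,0.876307,0.929776,0.968583,0.992115],"y":[-0.06,0.032753,0.128952,0.226732,0.323997,0.418484,0.507851,0.58976,0.661978,0.722469,0.769482,0.801629,0.817948,0.817948,0.801629,0.769482,0.722469,0.661978,0.58976,0.507851,0.418484,0.323997,0.226732,0.128952,0.032753,-0.06,-0.147727,-0.229161,-0.303367,-0.369729,-0.427927,-0.477897,-0.519779,-0.553854,-0.580482,-0.600039,-0.612865,-0.61921,-0.61921,-0.612865,-0.600039,-0.580482,-0.553854,-0.519779,-0.477897,-0.427927,-0.369729,-0.303367,-0.229161,-0.147727],"description":["synthetic 50-vertex thorax cross-section at the electrode plane (ventral = +y, arbitrary units)"]}
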