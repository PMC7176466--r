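## Regional respiratory-system mechanics: per-pixel dynamic compliance from
## tidal delta-Z and driving pressure, C_max / P* summaries across a protocol
## stage, overdistension/atelectasis fraction maps F(P), C_max-weighted step
## summaries, and EIT-versus-ventilator compliance correlation.

#' Driving pressure at the airway opening
#'
#' @param pPlat plateau pressure, cm H2O.
#' @param peep PEEP, cm H2O.
#' @return pPlat - peep.
#' @export
deltaPawo <- function(pPlat, peep) {
  if (any(pPlat <= peep)) stop("P_plat must exceed PEEP")
  pPlat - peep
}

#' Blood-gas recruitment criterion
#'
#' @param pao2 arterial oxygen partial pressure, mm Hg.
#' @param paco2 arterial carbon-dioxide partial pressure, mm Hg.
#' @return TRUE iff PaO2 + PaCO2 >= 400 mm Hg.
#' @export
recruitmentIndex <- function(pao2, paco2) {
  if (any(pao2 < 0) || any(paco2 < 0)) stop("blood-gas pressures must be nonnegative")
  pao2 + paco2 >= 400
}

#' Per-pixel dynamic compliance map
#'
#' @param tidalImage side x side tidal delta-Z image.
#' @param deltaP driving pressure, cm H2O (> 0).
#' @param roi an ROI mask (list with logical \code{mask}); pixels outside
#'   are NA.
#' @return side x side compliance matrix (delta-Z per cm H2O); negative
#'   values are retained.
#' @export
cdynMap <- function(tidalImage, deltaP, roi) {
  if (deltaP <= 0) stop("driving pressure must be positive")
  out <- tidalImage / deltaP
  out[!roi$mask] <- NA_real_
  out
}

#' Assemble a compliance stack across protocol steps
#'
#' @param cdynMaps list of \code{\link{cdynMap}} results, in acquisition
#'   order.
#' @param pressures stage-relevant pressure per step (plateau pressure
#'   during recruitment, PEEP during titration), cm H2O.
#' @param labels step labels.
#' @param stage stage scope label.
#' @param roi the aggregate ROI mask.
#' @return list of class \code{ComplianceStack}.
#' @export
complianceStack <- function(cdynMaps, pressures, labels, stage, roi) {
  stopifnot(length(cdynMaps) == length(pressures),
            length(labels) == length(pressures), all(pressures > 0))
  structure(
    list(maps = cdynMaps, pressures = pressures, labels = labels,
         stage = stage, roi = roi),
    class = "ComplianceStack"
  )
}

#' Maximum compliance and its pressure, per pixel
#'
#' C_max is the per-pixel maximum of C_dyn(P) over the stack; P* the
#' pressure at which it is achieved (ties resolve to the lowest tied
#' pressure). Pixels with C_max <= 0 are flagged invalid.
#'
#' @param stack a \code{\link{complianceStack}}.
#' @return list of class \code{ComplianceSummary}: \code{cmax}, \code{pstar}
#'   (matrices), logical \code{valid}, \code{stage}.
#' @export
cmaxPstar <- function(stack) {
  if (length(stack$maps) < 2L) stop("need at least 2 steps in scope")
  A <- simplify2array(stack$maps) # side x side x steps
  cmax <- apply(A, c(1, 2), function(z) if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
  pidx <- apply(A, c(1, 2), function(z) {
    if (all(is.na(z))) return(NA_integer_)
    m <- max(z, na.rm = TRUE)
    tied <- which(!is.na(z) & z == m)
    tied[which.min(stack$pressures[tied])]
  })
  pstar <- matrix(stack$pressures[pidx], nrow(cmax), ncol(cmax))
  valid <- !is.na(cmax) & cmax > 0
  pstar[!valid] <- NA_real_
  structure(
    list(cmax = cmax, pstar = pstar, valid = valid, stage = stack$stage,
         pressures = stack$pressures),
    class = "ComplianceSummary"
  )
}

#' Overdistension / atelectasis fraction map
#'
#' F(P) = (C_dyn(P) - C_max)/C_max for P < P* (atelectasis, negative) and
#' (C_max - C_dyn(P))/C_max for P >= P* (overdistension, positive), bounded
#' in [-1, 1]. Values exceeding the bounds by more than 1e-9 raise an
#' error; smaller numerical excess is clipped.
#'
#' @param stack a \code{\link{complianceStack}}.
#' @param summary the matching \code{\link{cmaxPstar}} result.
#' @param step step index or label within the stack.
#' @return list of class \code{ODAtelMap}: \code{F} matrix, \code{pressure},
#'   \code{stage}.
#' @export
odAtelMap <- function(stack, summary, step) {
  if (is.character(step)) step <- match(step, stack$labels)
  if (is.na(step) || step < 1L || step > length(stack$maps))
    stop("step not in stack")
  P <- stack$pressures[step]
  cd <- stack$maps[[step]]
  cm <- summary$cmax
  ps <- summary$pstar
  valid <- summary$valid
  if (any(valid & (is.na(cm) | cm == 0)))
    stop("C_max = 0 pixel reached; exclude invalid pixels first")
  Fv <- matrix(NA_real_, nrow(cd), ncol(cd))
  lower <- valid & P < ps
  upper <- valid & P >= ps
  Fv[lower] <- (cd[lower] - cm[lower]) / cm[lower]
  Fv[upper] <- (cm[upper] - cd[upper]) / cm[upper]
  excess <- pmax(Fv - 1, -1 - Fv, 0, na.rm = FALSE)
  if (any(excess > 1e-9, na.rm = TRUE))
    stop("F(P) out of [-1, 1] beyond numerical tolerance")
  Fv <- pmin(pmax(Fv, -1), 1)
  structure(list(F = Fv, pressure = P, stage = stack$stage, step = stack$labels[step]),
            class = "ODAtelMap")
}

#' Step summary: overdistension, atelectasis, fraction at maximum
#'
#' C_max-weighted pixel averages of the positive (overdistension) and
#' negative (atelectasis) parts of F over the ROI, in percent, plus the
#' percentage of ROI pixels whose P* equals the step pressure. An
#' unweighted variant is available via \code{weighted = FALSE}.
#'
#' @param map an \code{\link{odAtelMap}} result.
#' @param summary the matching \code{\link{cmaxPstar}} result.
#' @param weighted use C_max weighting (the default) or plain pixel
#'   averaging.
#' @return list: \code{od_pct}, \code{atel_pct}, \code{pct_at_max},
#'   \code{weighted}.
#' @export
stepSummary <- function(map, summary, weighted = TRUE) {
  sel <- summary$valid & !is.na(map$F)
  if (!any(sel)) stop("empty ROI")
  w <- if (weighted) summary$cmax[sel] else rep(1, sum(sel))
  Fv <- map$F[sel]
  od <- 100 * sum(w * pmax(Fv, 0)) / sum(w)
  atel <- 100 * sum(w * pmax(-Fv, 0)) / sum(w)
  atMax <- 100 * sum(summary$pstar[sel] == map$pressure) / sum(sel)
  list(od_pct = od, atel_pct = atel, pct_at_max = atMax, weighted = weighted)
}

#' Pearson correlation between EIT and ventilator compliance series
#'
#' @param eitSeries per-step whole-ROI mean dynamic compliance from EIT.
#' @param ventSeries per-step ventilator compliance.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
complianceCorrelation <- function(eitSeries, ventSeries) {
  if (length(eitSeries) != length(ventSeries)) stop("length mismatch")
  if (length(eitSeries) < 3L) stop("need at least 3 steps")
  if (sd(eitSeries) == 0 || sd(ventSeries) == 0) stop("zero variance")
  ct <- cor.test(eitSeries, ventSeries, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(eitSeries))
}
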