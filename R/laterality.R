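#' Hemispheric laterality index of an event type
#'
#' For stroke subjects the laterality index (LI) is the mean density over the
#' stroke electrodes divided by the mean density over the contralateral
#' electrodes (CM and CNM together by default; \code{denominator = "mirror"}
#' restricts to CM). For healthy subjects it is mean(left) / mean(right).
#' LI = 1 means the group means are equal.
#'
#' @param density density table from [computeDensity()].
#' @param groups an \linkS4class{ElectrodeGroups}.
#' @param eventType one of \code{"SO"}, \code{"delta"}, \code{"spindle"},
#'   \code{"SO_spindle"}, \code{"delta_spindle"}.
#' @param denominator \code{"all"} (CM + CNM) or \code{"mirror"} (CM only);
#'   ignored for healthy subjects.
#' @return a single number, or NA (with a warning) when the denominator mean
#'   is not positive.
#' @export
lateralityIndex <- function(density, groups, eventType,
                            denominator = c("all", "mirror")) {
  denominator <- match.arg(denominator)
  d <- density[density$event_type == eventType, ]
  if (length(groups@stroke)) {
    numCh <- groups@stroke
    denCh <- if (denominator == "mirror") groups@contralateralMirror
             else c(groups@contralateralMirror, groups@contralateralNonMirror)
  } else {
    numCh <- groups@left
    denCh <- groups@right
  }
  if (!length(numCh) || !length(denCh))
    stop("both electrode groups must be nonempty to compute an LI")
  num <- mean(d$density[d$channel %in% numCh])
  den <- mean(d$density[d$channel %in% denCh])
  if (!is.finite(den) || den <= 0) {
    warning("LI undefined for ", eventType,
            ": contralateral/right mean density is not positive")
    return(NA_real_)
  }
  num / den
}

#' Laterality indices of all event types plus the LI ratio
#'
#' Computes the LI of each of the five event types and the ratio of the
#' SO-nested-spindle LI to the delta-nested-spindle LI (the restorative /
#' pathological nesting balance; 1 = symmetric balance).
#'
#' @inheritParams lateralityIndex
#' @return data.frame with columns \code{subject}, \code{event_type}
#'   (five types plus \code{"li_ratio"}) and \code{value}.
#' @export
lateralityResult <- function(density, groups, denominator = c("all", "mirror")) {
  denominator <- match.arg(denominator)
  types <- c("SO", "delta", "spindle", "SO_spindle", "delta_spindle")
  li <- vapply(types, function(tt)
    lateralityIndex(density, groups, tt, denominator), numeric(1))
  data.frame(
    subject = density$subject[1],
    event_type = c(types, "li_ratio"),
    value = c(li, liRatio(li[["SO_spindle"]], li[["delta_spindle"]])),
    row.names = NULL)
}

#' Ratio of SO-nested to delta-nested spindle laterality indices
#'
#' @param liSO laterality index of SO-nested spindle density.
#' @param liDelta laterality index of delta-nested spindle density.
#' @return \code{liSO / liDelta}, or NA (with a warning) when either input is
#'   undefined or \code{liDelta} is not positive.
#' @export
liRatio <- function(liSO, liDelta) {
  if (!is.finite(liSO) || !is.finite(liDelta) || liDelta <= 0) {
    warning("LI ratio undefined (inputs missing or non-positive denominator)")
    return(NA_real_)
  }
  liSO / liDelta
}
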