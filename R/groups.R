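#' Resolve electrode groups from a configuration
#'
#' Stroke subjects configure \code{stroke}, \code{contralateral_mirror} and
#' \code{contralateral_non_mirror} label lists. Healthy subjects may omit
#' \code{left}/\code{right}, which are then inferred from 10-20 label parity
#' (odd terminal digit = left, even = right; midline \code{z} electrodes
#' belong to neither hemisphere).
#'
#' @param config named list of role -> character label vectors; recognized
#'   roles: \code{stroke}, \code{contralateral_mirror},
#'   \code{contralateral_non_mirror}, \code{left}, \code{right},
#'   \code{medication_group} (a single string).
#' @param channels available channel labels.
#' @return an \linkS4class{ElectrodeGroups}.
#' @examples
#' resolveGroups(list(stroke = c("C4", "P4"),
#'                    contralateral_mirror = c("C3", "P3"),
#'                    contralateral_non_mirror = c("F3", "O1"),
#'                    medication_group = "group2_levetiracetam"),
#'               c("C3", "C4", "P3", "P4", "F3", "O1"))
#' @export
resolveGroups <- function(config, channels) {
  channels <- normalizeChannelLabels(channels)
  pick <- function(role) {
    v <- normalizeChannelLabels(as.character(unlist(config[[role]])))
    unknown <- setdiff(v, channels)
    if (length(unknown))
      stop("group '", role, "' refers to unknown channels: ",
           paste(unknown, collapse = ", "))
    v
  }
  stroke <- pick("stroke")
  cm <- pick("contralateral_mirror")
  cnm <- pick("contralateral_non_mirror")
  left <- pick("left")
  right <- pick("right")
  med <- config$medication_group
  if (is.null(med)) med <- if (length(stroke)) "group3_other" else "healthy"

  assigned <- c(stroke, cm, cnm)
  if (anyDuplicated(assigned))
    stop("channel(s) assigned to more than one group: ",
         paste(unique(assigned[duplicated(assigned)]), collapse = ", "))
  if (!length(stroke) && !length(left) && !length(right)) {
    left <- channels[hemisphereOf(channels) == "left"]
    right <- channels[hemisphereOf(channels) == "right"]
  }
  new("ElectrodeGroups", stroke = stroke, contralateralMirror = cm,
      contralateralNonMirror = cnm, left = left, right = right,
      medicationGroup = med)
}

#' Hemisphere of a 10-20 label
#'
#' Odd terminal digit = left, even = right, trailing \code{Z} = midline.
#'
#' @param labels character vector of 10-20 labels.
#' @return character vector in \code{c("left", "right", "midline")}.
#' @export
hemisphereOf <- function(labels) {
  labels <- normalizeChannelLabels(labels)
  out <- rep("midline", length(labels))
  digit <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", labels)))
  out[!is.na(digit) & digit %% 2L == 1L] <- "left"
  out[!is.na(digit) & digit %% 2L == 0L] <- "right"
  out
}

#' Mirror electrode of a 10-20 label
#'
#' Swaps the hemisphere by incrementing/decrementing the terminal digit
#' (C3 <-> C4, F7 <-> F8, FP1 <-> FP2, ...). Midline labels map to themselves.
#'
#' @param labels character vector of 10-20 labels.
#' @return character vector of mirrored labels.
#' @export
mirrorElectrode <- function(labels) {
  labels <- normalizeChannelLabels(labels)
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexec("^(.*?)(\\d+)$", lab))[[1]]
    if (length(m) < 3) return(lab)
    d <- as.integer(m[3])
    paste0(m[2], if (d %% 2L == 1L) d + 1L else d - 1L)
  }, "", USE.NAMES = FALSE)
}

#' Read / write an electrode-group + run configuration file
#'
#' A single human-editable YAML file holding the reference scheme, electrode
#' groups and any detector overrides.
#'
#' @param path YAML file.
#' @return \code{readGroupsConfig}: the named list; \code{writeGroupsConfig}:
#'   the path, invisibly.
#' @export
readGroupsConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  yaml::read_yaml(path)
}

#' @rdname readGroupsConfig
#' @param config named list to serialize.
#' @export
writeGroupsConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
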