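#' Describe the TMT channel layout of a dual-compartment labeling experiment
#'
#' A channel design assigns every TMT reporter channel to a condition --
#' `"ENDO"` (endosome-targeted peroxidase), `"SURF"` (surface-targeted
#' peroxidase) or `"NC"` (negative control lacking enzyme or peroxide) --
#' and a replicate index within that condition.
#'
#' The design used throughout the package by default is the 8-plex layout of
#' the profiling experiment: three ENDO replicates, three SURF replicates and
#' two negative controls.
#'
#' @param channels character vector of unique channel labels, in plex order.
#' @param condition character vector, one of `"ENDO"`, `"SURF"`, `"NC"` per
#'   channel.
#' @param replicate positive integer replicate index per channel (1-based
#'   within condition).
#' @return An object of class `channel_design`: a data frame with columns
#'   `channel`, `condition`, `replicate`.
#' @seealso [validate_design()] for the invariant checks.
#' @examples
#' design <- default_channel_design()
#' validate_design(design)          # character(0): all invariants hold
#' experimental_channels(design)
#' @export
channel_design <- function(channels, condition, replicate) {
  if (length(channels) != length(condition) ||
      length(channels) != length(replicate)) {
    ep_validation_error("channels, condition and replicate must have equal length")
  }
  d <- data.frame(
    channel = as.character(channels),
    condition = as.character(condition),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  class(d) <- c("channel_design", "data.frame")
  d
}

#' @rdname channel_design
#' @export
default_channel_design <- function() {
  channel_design(
    channels  = c("ENDO_1", "ENDO_2", "ENDO_3",
                  "SURF_1", "SURF_2", "SURF_3",
                  "NC_1", "NC_2"),
    condition = c(rep("ENDO", 3), rep("SURF", 3), rep("NC", 2)),
    replicate = c(1:3, 1:3, 1:2)
  )
}

#' Check a channel design against its invariants
#'
#' Validation is total: it never throws, it returns findings. An empty
#' character vector means the design is valid. Checked invariants: channel
#' labels unique; conditions restricted to ENDO/SURF/NC; exactly two
#' negative-control channels; at least two replicates per experimental
#' condition; replicate indices positive and unique within condition.
#'
#' @param design a [channel_design()].
#' @return character vector of findings, one per violated invariant;
#'   `character(0)` if valid.
#' @export
validate_design <- function(design) {
  findings <- character(0)
  if (!inherits(design, "channel_design")) {
    return("not a channel_design object")
  }
  if (anyDuplicated(design$channel)) {
    findings <- c(findings, "channel ids must be unique")
  }
  bad <- setdiff(unique(design$condition), c("ENDO", "SURF", "NC"))
  if (length(bad)) {
    findings <- c(findings, paste0(
      "unknown condition(s): ", paste(bad, collapse = ", ")))
  }
  if (sum(design$condition == "NC") != 2L) {
    findings <- c(findings, "requires exactly 2 NC channels")
  }
  for (cond in intersect(c("ENDO", "SURF"), design$condition)) {
    if (sum(design$condition == cond) < 2L) {
      findings <- c(findings, paste0(
        "condition ", cond, " requires >= 2 replicates"))
    }
  }
  if (!all(c("ENDO", "SURF") %in% design$condition)) {
    findings <- c(findings, "both ENDO and SURF conditions must be present")
  }
  if (any(!is.finite(design$replicate)) || any(design$replicate < 1L)) {
    findings <- c(findings, "replicate indices must be positive integers")
  } else {
    for (cond in unique(design$condition)) {
      reps <- design$replicate[design$condition == cond]
      if (anyDuplicated(reps)) {
        findings <- c(findings, paste0(
          "replicate indices must be unique within condition ", cond))
      }
    }
  }
  findings
}

assert_valid_design <- function(design) {
  findings <- validate_design(design)
  if (length(findings)) {
    ep_validation_error(paste0(
      "invalid channel design: ", paste(findings, collapse = "; ")))
  }
  invisible(design)
}

#' Channel accessors
#'
#' @param design a [channel_design()].
#' @param condition one of `"ENDO"`, `"SURF"`.
#' @return character vector of channel labels.
#' @export
condition_channels <- function(design, condition) {
  design$channel[design$condition == condition]
}

#' @rdname condition_channels
#' @export
nc_channels <- function(design) condition_channels(design, "NC")

#' @rdname condition_channels
#' @export
experimental_channels <- function(design) {
  design$channel[design$condition != "NC"]
}
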