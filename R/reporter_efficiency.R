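# Reporter-gene quantification arithmetic: specific enzyme activities and
# transcript levels to normalized translational efficiencies.

#' Translational efficiency of a reporter measurement
#'
#' Background-corrected specific activity divided by the relative transcript
#' level: `(specific_activity − control_activity) / transcript_level`. The
#' control (empty-vector strain) average is subtracted from the activities
#' only; values below control come out negative and are reported, not
#' clipped.
#'
#' @param specific_activity numeric, kat per mg protein.
#' @param control_activity scalar mean activity of the empty-vector control.
#' @param transcript_level numeric, signal normalized to 16S rRNA; must be
#'   positive.
#' @return numeric efficiencies (dimensionless).
#' @export
translational_efficiency <- function(specific_activity, control_activity,
                                     transcript_level) {
  if (any(!is.finite(transcript_level)) || any(transcript_level <= 0)) {
    stop("transcript_level must be positive", call. = FALSE)
  }
  (specific_activity - control_activity) / transcript_level
}

#' Normalize per-construct efficiencies to the wildtype
#'
#' Divides every replicate efficiency by the wildtype construct's mean
#' efficiency (so the wildtype maps to 1.0) and reports per-construct mean
#' and sample standard deviation over biological replicates.
#'
#' @param efficiencies tibble with `construct_id` and `efficiency` columns
#'   (one row per replicate).
#' @param wildtype_id construct id of the wildtype.
#' @return tibble with `construct_id`, `mean_norm_eff`, `sd_norm_eff`,
#'   `n_replicates`.
#' @export
normalize_to_wildtype <- function(efficiencies, wildtype_id) {
  efficiencies <- tibble::as_tibble(efficiencies)
  stopifnot(all(c("construct_id", "efficiency") %in% names(efficiencies)))
  wt <- efficiencies$efficiency[efficiencies$construct_id == wildtype_id]
  if (length(wt) == 0) stop("wildtype construct not present", call. = FALSE)
  wt_mean <- mean(wt)
  if (wt_mean == 0) stop("wildtype efficiency is zero", call. = FALSE)
  efficiencies |>
    dplyr::mutate(norm = .data$efficiency / wt_mean) |>
    dplyr::group_by(.data$construct_id) |>
    dplyr::summarise(
      mean_norm_eff = mean(.data$norm),
      sd_norm_eff = stats::sd(.data$norm),
      n_replicates = dplyr::n()
    ) |>
    dplyr::ungroup()
}

#' Reporter-efficiency pipeline over a measurement table
#'
#' Computes the control mean activity from the control construct's rows,
#' turns every measurement into a translational efficiency, and normalizes
#' to the wildtype.
#'
#' @param measurements tibble with `construct_id`, `replicate`,
#'   `specific_activity`, `transcript_level`.
#' @param control_id construct id of the empty-vector negative control.
#' @param wildtype_id construct id of the wildtype.
#' @return tibble as in [normalize_to_wildtype()] (control rows excluded).
#' @export
reporter_efficiency_table <- function(measurements, control_id, wildtype_id) {
  measurements <- tibble::as_tibble(measurements)
  required <- c("construct_id", "replicate", "specific_activity",
                "transcript_level")
  stopifnot(all(required %in% names(measurements)))
  ctrl <- measurements$specific_activity[measurements$construct_id == control_id]
  if (length(ctrl) == 0) stop("control construct not present", call. = FALSE)
  samples <- measurements[measurements$construct_id != control_id, , drop = FALSE]
  eff <- tibble::tibble(
    construct_id = samples$construct_id,
    efficiency = translational_efficiency(
      samples$specific_activity, mean(ctrl), samples$transcript_level)
  )
  normalize_to_wildtype(eff, wildtype_id)
}
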