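#' @title Clinically assayed cytogenetic events
#' @description The ten alterations routinely assayed by FISH in multiple
#'   myeloma: arm-level losses del(1p), del(13q), del(14q), del(17p), the
#'   arm-level gain gain(1q), and the five IGH translocations t(4;14),
#'   t(6;14), t(11;14), t(14;16), t(14;20). SV calls support an arm event
#'   when a deletion (loss) or duplication (gain) overlaps the arm, and a
#'   translocation event when a paired breakend joins the two chromosomes.
#' @name cytogenetics
NULL

#' Build the ten-event panel
#'
#' @param arms Arm tibble from [read_arm_map()] / [default_arm_map()];
#'   must contain chromosomes 1, 13, 14 and 17.
#' @param min_sv_size Minimum supporting SV size in bp for arm events.
#'   Default 0 (any overlapping call counts).
#' @return Tibble with columns `event_id`, `kind` (`arm_loss`, `arm_gain`,
#'   `translocation`), `chrom`, `start`, `end` (arm events), `chrom_pair`
#'   (translocation events) and `min_sv_size`.
#' @export
build_event_panel <- function(arms = default_arm_map(), min_sv_size = 0) {
  arm_events <- tibble::tribble(
    ~event_id,   ~kind,      ~chrom, ~arm,
    "del(1p)",   "arm_loss",  "1",   "p",
    "gain(1q)",  "arm_gain",  "1",   "q",
    "del(13q)",  "arm_loss",  "13",  "q",
    "del(14q)",  "arm_loss",  "14",  "q",
    "del(17p)",  "arm_loss",  "17",  "p"
  )
  need <- unique(arm_events[, c("chrom", "arm")])
  have <- paste(arms$chrom, arms$arm)
  missing <- need[!paste(need$chrom, need$arm) %in% have, ]
  if (nrow(missing) > 0) {
    stop("arm map lacks required arm(s): ",
         paste(missing$chrom, missing$arm, sep = "", collapse = ", "))
  }
  arm_events <- dplyr::left_join(arm_events, arms, by = c("chrom", "arm"))
  partners <- c("4", "6", "11", "16", "20")
  tra <- tibble::tibble(
    event_id = sprintf("t(%s;14)", partners),
    kind = "translocation",
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    chrom_pair = canonical_chrom_pair(partners, rep("14", 5))
  )
  tra$event_id[partners == "16"] <- "t(14;16)"
  tra$event_id[partners == "20"] <- "t(14;20)"
  panel <- dplyr::bind_rows(
    dplyr::mutate(
      dplyr::select(arm_events, "event_id", "kind", "chrom", "start", "end"),
      chrom_pair = NA_character_
    ),
    tra
  )
  panel$min_sv_size <- min_sv_size
  panel
}

#' Score panel events for one callset
#'
#' Counts supporting SV calls per panel event: deletions overlapping the
#' arm for losses, duplications for gains (>= 1 bp overlap and size >=
#' `min_sv_size`), and paired inter-chromosomal breakend events joining the
#' event's chromosome pair for translocations. By default only calls
#' passing the caller's quality filter contribute.
#'
#' @param callset An [sv_callset()] (breakends are paired on the fly).
#' @param panel Panel tibble from [build_event_panel()].
#' @param pass_only Count only FILTER == PASS calls? Default `TRUE`.
#' @return Tibble with columns `sample`, `method`, `event_id`, `score`.
#' @export
detect_events <- function(callset, panel, pass_only = TRUE) {
  stopifnot(inherits(callset, "sv_callset"))
  if (!callset$paired) callset <- pair_breakends(callset)
  recs <- callset$records[callset$records$svtype %in% c("DEL", "DUP"), , drop = FALSE]
  if (pass_only) recs <- recs[recs$filter == "PASS", , drop = FALSE]
  tra <- callset$translocations[callset$translocations$inter, , drop = FALSE]
  if (pass_only) tra <- tra[tra$pass, , drop = FALSE]

  score <- vapply(seq_len(nrow(panel)), function(i) {
    ev <- panel[i, ]
    if (ev$kind == "translocation") {
      return(sum(tra$chrom_pair == ev$chrom_pair))
    }
    want <- if (ev$kind == "arm_loss") "DEL" else "DUP"
    r <- recs[recs$svtype == want & recs$chrom == ev$chrom, , drop = FALSE]
    if (nrow(r) == 0) return(0L)
    ov <- pmax(0, pmin(r$end, ev$end) - pmax(r$start, ev$start))
    sum(ov > 0 & (r$end - r$start) >= ev$min_sv_size)
  }, numeric(1))

  tibble::tibble(
    sample = callset$sample, method = callset$method,
    event_id = panel$event_id, score = as.integer(score)
  )
}

#' Build a prediction matrix from many callsets
#'
#' Concatenates [detect_events()] rows for a list of callsets; callsets
#' from different platforms form separate per-method matrices within the
#' long result.
#'
#' @param callsets List of [sv_callset()] objects, one per (sample,
#'   method).
#' @inheritParams detect_events
#' @return Long tibble with columns `sample`, `method`, `event_id`,
#'   `score`.
#' @export
build_prediction_matrix <- function(callsets, panel, pass_only = TRUE) {
  if (length(callsets) == 0) stop("no callsets supplied")
  keys <- vapply(callsets, function(x) paste(x$sample, x$method, sep = "\r"), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (sample, method) callset(s): ",
         paste(unique(gsub("\r", "/", keys[duplicated(keys)])), collapse = ", "))
  }
  purrr::map_dfr(callsets, detect_events, panel = panel, pass_only = pass_only)
}

#' Widen a long prediction (or truth) table
#'
#' @param x Long tibble with `sample`, `event_id` and a value column.
#' @param value Name of the value column, default `"score"`.
#' @return Wide tibble, one row per sample, one column per event.
#' @export
prediction_matrix_wide <- function(x, value = "score") {
  tidyr::pivot_wider(x, id_cols = "sample", names_from = "event_id",
                     values_from = dplyr::all_of(value))
}
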