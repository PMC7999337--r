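#' @title SV hotspot annotation
#' @description Annotates SV calls against a catalog of recurrently
#'   rearranged regions (categorized gain / loss / fragile) and computes
#'   per-sample hotspot burdens. By default an SV hits a hotspot when at
#'   least one of its breakpoints (the interval endpoints, or either
#'   breakend of a translocation) lies inside the region; whole-interval
#'   overlap semantics are selectable.
#' @name hotspots
NULL

# breakpoint positions of every countable feature in a callset:
# tibble(record_id, chrom, pos, start, end) — start/end NA for breakends
callset_breakpoints_ <- function(callset, pass_only) {
  if (!callset$paired) callset <- pair_breakends(callset)
  recs <- callset$records[callset$records$svtype != "BND", , drop = FALSE]
  if (pass_only) recs <- recs[recs$filter == "PASS", , drop = FALSE]
  iv <- dplyr::bind_rows(
    tibble::tibble(record_id = recs$record_id, chrom = recs$chrom,
                   pos = recs$start, start = recs$start, end = recs$end),
    tibble::tibble(record_id = recs$record_id, chrom = recs$chrom,
                   pos = recs$end - 1L, start = recs$start, end = recs$end)
  )
  tra <- callset$translocations
  if (pass_only) tra <- tra[tra$pass, , drop = FALSE]
  unp <- callset$unpaired
  if (pass_only) unp <- unp[unp$filter == "PASS", , drop = FALSE]
  bnd <- dplyr::bind_rows(
    tibble::tibble(record_id = tra$id_a, chrom = tra$chrom_a, pos = tra$pos_a,
                   start = NA_integer_, end = NA_integer_),
    tibble::tibble(record_id = tra$id_a, chrom = tra$chrom_b, pos = tra$pos_b,
                   start = NA_integer_, end = NA_integer_),
    tibble::tibble(record_id = unp$record_id, chrom = unp$chrom, pos = unp$start,
                   start = NA_integer_, end = NA_integer_)
  )
  dplyr::bind_rows(iv, bnd)
}

#' Annotate a callset against a hotspot catalog
#'
#' @param callset An [sv_callset()].
#' @param catalog Catalog tibble from [read_hotspot_catalog()].
#' @param mode `"breakpoint"` (default): an SV hits a hotspot iff one of
#'   its breakpoints lies inside the region. `"overlap"`: any >= 1 bp
#'   interval overlap counts (breakends still by containment).
#' @param pass_only Use only FILTER == PASS calls? Default `TRUE`.
#' @return Tibble with one row per (sample, hotspot) hit: `sample`,
#'   `hotspot_id`, `category`, `n_supporting`, `record_ids`
#'   (comma-separated). A hotspot is counted once per sample regardless of
#'   how many calls support it.
#' @export
annotate_hotspots <- function(callset, catalog, mode = c("breakpoint", "overlap"),
                              pass_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(callset, "sv_callset"))
  empty <- tibble::tibble(sample = character(), hotspot_id = character(),
                          category = character(), n_supporting = integer(),
                          record_ids = character())
  if (nrow(catalog) == 0) return(empty)
  bp <- callset_breakpoints_(callset, pass_only)
  if (nrow(bp) == 0) return(empty)
  pairs <- dplyr::inner_join(bp, catalog, by = "chrom",
                             relationship = "many-to-many",
                             suffix = c("", "_hs"))
  hit <- if (mode == "breakpoint") {
    pairs$pos >= pairs$start_hs & pairs$pos < pairs$end_hs
  } else {
    ifelse(is.na(pairs$start),
           pairs$pos >= pairs$start_hs & pairs$pos < pairs$end_hs,
           pmin(pairs$end, pairs$end_hs) - pmax(pairs$start, pairs$start_hs) > 0)
  }
  pairs <- pairs[hit, , drop = FALSE]
  if (nrow(pairs) == 0) return(empty)
  pairs |>
    dplyr::distinct(.data$hotspot_id, .data$category, .data$record_id) |>
    dplyr::group_by(.data$hotspot_id, .data$category) |>
    dplyr::summarise(
      n_supporting = dplyr::n_distinct(.data$record_id),
      record_ids = paste(sort(unique(.data$record_id)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::mutate(sample = callset$sample, .before = 1)
}

#' Per-sample hotspot burden counts
#'
#' @param hits Hit tibble from [annotate_hotspots()] (possibly
#'   row-bound across samples).
#' @param samples Optional character vector of cohort samples to report,
#'   including zero-burden ones.
#' @return Tibble with per-sample `gain`, `loss`, `fragile`, `total` counts
#'   and the corresponding proportions (`NA` when total is 0).
#' @export
hotspot_counts <- function(hits, samples = NULL) {
  samples <- samples %||% unique(hits$sample)
  counts <- hits |>
    dplyr::count(.data$sample, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  out <- tibble::tibble(sample = samples) |>
    dplyr::left_join(counts, by = "sample")
  for (cc in c("gain", "loss", "fragile")) {
    if (!cc %in% names(out)) out[[cc]] <- 0L
    out[[cc]][is.na(out[[cc]])] <- 0L
  }
  out$total <- out$gain + out$loss + out$fragile
  for (cc in c("gain", "loss", "fragile")) {
    out[[paste0("prop_", cc)]] <- ifelse(out$total > 0, out[[cc]] / out$total, NA_real_)
  }
  out[, c("sample", "gain", "loss", "fragile", "total",
          "prop_gain", "prop_loss", "prop_fragile")]
}

#' Cohort-level hotspot burden summary
#'
#' @param counts Per-sample counts from [hotspot_counts()].
#' @return One-row tibble with `n_samples`, `median_hotspots` and
#'   `mean_hotspots` (standard median: mean of the middle pair for even n).
#' @export
cohort_summary <- function(counts) {
  if (nrow(counts) == 0) stop("empty cohort: no samples to summarise")
  tibble::tibble(
    n_samples = nrow(counts),
    median_hotspots = stats::median(counts$total),
    mean_hotspots = mean(counts$total)
  )
}
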