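#' @title Callset concordance by reciprocal overlap
#' @description Type-stratified comparison of two SV callsets from the same
#'   sample. Interval SVs (DEL/DUP/INV) match under a reciprocal-overlap
#'   rule (default 70% of both spans); insertions match by insertion-point
#'   proximity; translocations match by chromosome pair and per-breakend
#'   distance. "Shared" counts unique A-side features with at least one
#'   qualifying B match, mirroring the directional convention of
#'   bedtools-style comparisons.
#' @name concordance
NULL

#' Matching configuration
#'
#' @param fraction Reciprocal overlap threshold F in (0, 1]. Default 0.70.
#' @param reciprocal Require the overlap to reach F of *both* spans
#'   (bedtools `-f F -r`)? If `FALSE`, only the A-side fraction is tested.
#' @param translocation_window Per-breakend tolerance in bp for
#'   translocation matching. Default 10000.
#' @param require_same_type Match only records of the same SV type? Default
#'   `TRUE`.
#' @param ins_window Insertion-point distance tolerance in bp for INS
#'   matching (reciprocal span overlap is undefined for point insertions).
#'   Default 50.
#' @return A `match_config` list.
#' @export
match_config <- function(fraction = 0.70, reciprocal = TRUE,
                         translocation_window = 10000,
                         require_same_type = TRUE, ins_window = 50) {
  stopifnot(fraction > 0, fraction <= 1, translocation_window >= 0, ins_window >= 0)
  structure(
    list(
      fraction = fraction, reciprocal = reciprocal,
      translocation_window = translocation_window,
      require_same_type = require_same_type, ins_window = ins_window
    ),
    class = "match_config"
  )
}

#' Reciprocal overlap fractions of two intervals
#'
#' Vectorized over its arguments. Intervals on different chromosomes have
#' fractions (0, 0). Swapping the arguments exchanges the two components.
#'
#' @param chrom_a,start_a,end_a First interval(s), 0-based half-open.
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Tibble with columns `frac_a` (= |a∩b|/|a|) and `frac_b`
#'   (= |a∩b|/|b|), both in \[0, 1\].
#' @export
reciprocal_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  stopifnot(all(start_a < end_a), all(start_b < end_b))
  ov <- pmax(0, pmin(end_a, end_b) - pmax(start_a, start_b))
  ov <- ifelse(chrom_a == chrom_b, ov, 0)
  tibble::tibble(frac_a = ov / (end_a - start_a), frac_b = ov / (end_b - start_b))
}

# qualifying A->B match pairs among interval/INS records; returns tibble
# with columns idx_a, idx_b (row indices into a_rec / b_rec)
match_pairs_ <- function(a_rec, b_rec, cfg) {
  a <- dplyr::mutate(a_rec, .idx_a = dplyr::row_number())
  b <- dplyr::mutate(b_rec, .idx_b = dplyr::row_number())
  key <- if (cfg$require_same_type) c("chrom", "svtype") else "chrom"
  pairs <- dplyr::inner_join(
    dplyr::select(a, ".idx_a", "chrom", svtype_a = "svtype",
                  start_a = "start", end_a = "end"),
    dplyr::select(b, ".idx_b", "chrom", svtype_b = "svtype",
                  start_b = "start", end_b = "end"),
    by = if (cfg$require_same_type) {
      c("chrom", "svtype_a" = "svtype_b")
    } else "chrom",
    relationship = "many-to-many", suffix = c("_a", "_b")
  )
  if (nrow(pairs) == 0) return(tibble::tibble(idx_a = integer(), idx_b = integer()))
  point_a <- if (cfg$require_same_type) pairs$svtype_a == "INS" else {
    a$svtype[pairs$.idx_a] == "INS" | b$svtype[pairs$.idx_b] == "INS"
  }
  fr <- reciprocal_overlap(pairs$chrom, pairs$start_a, pairs$end_a,
                           pairs$chrom, pairs$start_b, pairs$end_b)
  span_ok <- if (cfg$reciprocal) {
    fr$frac_a >= cfg$fraction & fr$frac_b >= cfg$fraction
  } else {
    fr$frac_a >= cfg$fraction
  }
  ins_ok <- abs(pairs$start_a - pairs$start_b) <= cfg$ins_window
  ok <- ifelse(point_a, ins_ok, span_ok)
  tibble::tibble(idx_a = pairs$.idx_a[ok], idx_b = pairs$.idx_b[ok])
}

#' Match two SV callsets
#'
#' Produces the per-type concordance table between callsets A and B:
#' `shared` is the number of unique A features with at least one qualifying
#' B match of the same type; `a_only = n_a - shared`; `b_only` is the
#' number of B features with no qualifying A match. BND records are routed
#' to [match_translocations()] and reported in the `BND` row (breakends are
#' paired on the fly if needed).
#'
#' @param a,b [sv_callset()] objects from the same sample.
#' @param cfg A [match_config()].
#' @param allow_sample_mismatch Compare callsets from different samples?
#'   Default `FALSE` (error).
#' @return Tibble with columns `svtype`, `n_a`, `n_b`, `shared`, `a_only`,
#'   `b_only`.
#' @export
match_callsets <- function(a, b, cfg = match_config(), allow_sample_mismatch = FALSE) {
  stopifnot(inherits(a, "sv_callset"), inherits(b, "sv_callset"))
  if (!allow_sample_mismatch && !identical(a$sample, b$sample)) {
    stop("callsets are from different samples ('", a$sample, "' vs '", b$sample,
         "'); set allow_sample_mismatch = TRUE to override")
  }
  a_rec <- a$records[a$records$svtype != "BND", , drop = FALSE]
  b_rec <- b$records[b$records$svtype != "BND", , drop = FALSE]
  pairs <- match_pairs_(a_rec, b_rec, cfg)
  types <- setdiff(SVTYPES, "BND")
  per_type <- purrr::map_dfr(types, function(tt) {
    ia <- which(a_rec$svtype == tt)
    ib <- which(b_rec$svtype == tt)
    shared <- length(intersect(pairs$idx_a, ia))
    b_matched <- length(intersect(pairs$idx_b, ib))
    tibble::tibble(
      svtype = tt, n_a = length(ia), n_b = length(ib),
      shared = shared, a_only = length(ia) - shared,
      b_only = length(ib) - b_matched
    )
  })
  dplyr::bind_rows(per_type, match_translocations(a, b, cfg))
}

#' Match translocation events between two callsets
#'
#' An A event matches a B event iff their canonical chromosome pairs are
#' equal and each corresponding breakend lies within
#' `cfg$translocation_window` bp. Breakend correspondence is resolved by
#' chromosome; for intra-chromosomal events the assignment minimizing the
#' maximum displacement is used.
#'
#' @inheritParams match_callsets
#' @return One-row tibble (`svtype = "BND"`) with `n_a`, `n_b`, `shared`,
#'   `a_only`, `b_only` counted over translocation events.
#' @export
match_translocations <- function(a, b, cfg = match_config()) {
  if (!a$paired) a <- pair_breakends(a)
  if (!b$paired) b <- pair_breakends(b)
  ta <- a$translocations
  tb <- b$translocations
  W <- cfg$translocation_window
  event_match <- function(ea, eb) {
    if (ea$chrom_pair != eb$chrom_pair) return(FALSE)
    if (ea$chrom_a != ea$chrom_b) {
      # correspondence forced by chromosome identity
      if (ea$chrom_a == eb$chrom_a) {
        d <- max(abs(ea$pos_a - eb$pos_a), abs(ea$pos_b - eb$pos_b))
      } else {
        d <- max(abs(ea$pos_a - eb$pos_b), abs(ea$pos_b - eb$pos_a))
      }
    } else {
      d <- min(
        max(abs(ea$pos_a - eb$pos_a), abs(ea$pos_b - eb$pos_b)),
        max(abs(ea$pos_a - eb$pos_b), abs(ea$pos_b - eb$pos_a))
      )
    }
    d <= W
  }
  hit_a <- logical(nrow(ta))
  hit_b <- logical(nrow(tb))
  if (nrow(ta) > 0 && nrow(tb) > 0) {
    for (i in seq_len(nrow(ta))) {
      for (j in seq_len(nrow(tb))) {
        if (event_match(ta[i, ], tb[j, ])) {
          hit_a[i] <- TRUE
          hit_b[j] <- TRUE
        }
      }
    }
  }
  tibble::tibble(
    svtype = "BND", n_a = nrow(ta), n_b = nrow(tb),
    shared = sum(hit_a), a_only = sum(!hit_a), b_only = sum(!hit_b)
  )
}

#' Type composition of a callset
#'
#' Proportion of calls per SV type. Features are counted as: one per
#' interval/insertion record, one per assembled translocation event, one
#' per unpaired breakend (breakends are paired on the fly if needed).
#'
#' @param callset An [sv_callset()].
#' @return Tibble with columns `svtype`, `n`, `proportion`; proportions sum
#'   to 1.
#' @export
type_composition <- function(callset) {
  stopifnot(inherits(callset, "sv_callset"))
  if (!callset$paired) callset <- pair_breakends(callset)
  n_iv <- table(factor(
    callset$records$svtype[callset$records$svtype != "BND"],
    levels = setdiff(SVTYPES, "BND")
  ))
  n_bnd <- nrow(callset$translocations) + nrow(callset$unpaired)
  out <- tibble::tibble(
    svtype = SVTYPES,
    n = c(as.integer(n_iv[setdiff(SVTYPES, "BND")]), n_bnd)
  )
  total <- sum(out$n)
  if (total == 0) stop("empty callset: type composition undefined")
  out$proportion <- out$n / total
  out
}
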