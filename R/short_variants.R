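#' @title Somatic short-variant filter cascade and overlaps
#' @description The post-calling filter cascade for annotated somatic
#'   short variants (caller filter, genomic region, exonic function,
#'   population allele frequency, quality, depth, VAF window, strand odds
#'   ratio), with per-rule removal accounting; three-way dataset overlap of
#'   normalized variants; and the MM driver-gene presence matrix.
#' @name short_variants
NULL

FILTER_RULES <- c("caller_filter", "region", "exonic_function", "pop_af",
                  "qual", "depth", "vaf", "sor")

MM_DRIVER_GENES <- c("BRAF", "KRAS", "NRAS", "TP53", "FAM46C")
SHORT_VARIANT_DATASETS <- c("linked-read", "WES", "RNA-seq")

#' Filter cascade configuration
#'
#' Defaults implement the standard somatic post-filter: drop variants not
#' passing all caller filters, intronic/intergenic variants,
#' synonymous/nonframeshift variants, variants with any population allele
#' frequency above 1%, calling quality below 40, depth below 10 reads, VAF
#' outside \[2%, 30%\], or strand odds ratio above 3 (SNV) / 11 (indel).
#'
#' @param require_pass Drop variants whose caller filter is not PASS?
#' @param drop_region Region classes removed.
#' @param drop_function Exonic function classes removed.
#' @param max_pop_af Maximum allowed population allele frequency (all
#'   populations).
#' @param min_qual Minimum calling quality.
#' @param min_depth Minimum read depth.
#' @param vaf_min,vaf_max Retained VAF window (inclusive).
#' @param max_sor_snv,max_sor_indel Maximum strand odds ratio by class.
#' @return A `filter_config` list; `rules` records the application order.
#' @export
filter_config <- function(require_pass = TRUE,
                          drop_region = c("intronic", "intergenic"),
                          drop_function = c("synonymous", "nonframeshift"),
                          max_pop_af = 0.01, min_qual = 40, min_depth = 10,
                          vaf_min = 0.02, vaf_max = 0.30,
                          max_sor_snv = 3, max_sor_indel = 11) {
  stopifnot(max_pop_af >= 0, min_qual >= 0, min_depth >= 0,
            vaf_min <= vaf_max, max_sor_snv > 0, max_sor_indel > 0)
  structure(
    list(
      require_pass = require_pass, drop_region = drop_region,
      drop_function = drop_function, max_pop_af = max_pop_af,
      min_qual = min_qual, min_depth = min_depth,
      vaf_min = vaf_min, vaf_max = vaf_max,
      max_sor_snv = max_sor_snv, max_sor_indel = max_sor_indel,
      rules = FILTER_RULES
    ),
    class = "filter_config"
  )
}

variant_class_ <- function(variants) {
  if ("variant_class" %in% names(variants) && !all(is.na(variants$variant_class))) {
    return(variants$variant_class)
  }
  dplyr::case_when(
    nchar(variants$ref) == 1 & nchar(variants$alt) == 1 ~ "SNV",
    nchar(variants$alt) > nchar(variants$ref) ~ "insertion",
    TRUE ~ "deletion"
  )
}

# per-rule pass/fail matrix (TRUE = fails the rule); columns in rule order
rule_failures_ <- function(variants, cfg) {
  n <- nrow(variants)
  af_cols <- intersect(c("af_exac", "af_esp", "af_1kg"), names(variants))
  af <- if (length(af_cols) > 0) {
    m <- as.matrix(variants[, af_cols])
    m[is.na(m)] <- 0            # absent population AF = novel variant
    apply(m, 1, max)
  } else {
    rep(0, n)
  }
  vclass <- variant_class_(variants)
  for (col in c("qual", "depth", "vaf", "sor")) {
    if (any(is.na(variants[[col]]))) {
      stop("missing ", col, " at variant row(s): ",
           paste(utils::head(which(is.na(variants[[col]])), 10), collapse = ", "))
    }
  }
  sor_cap <- ifelse(vclass == "SNV", cfg$max_sor_snv, cfg$max_sor_indel)
  cbind(
    caller_filter = if (cfg$require_pass) variants$filters != "PASS" else rep(FALSE, n),
    region = variants$region_class %in% cfg$drop_region,
    exonic_function = variants$exonic_function %in% cfg$drop_function,
    pop_af = af > cfg$max_pop_af,
    qual = variants$qual < cfg$min_qual,
    depth = variants$depth < cfg$min_depth,
    vaf = variants$vaf < cfg$vaf_min | variants$vaf > cfg$vaf_max,
    sor = variants$sor > sor_cap
  )
}

#' Apply the somatic filter cascade
#'
#' Rules are applied in the declared order; a removed variant is attributed
#' to the first rule it fails. The kept set is order-invariant (a variant
#' is kept iff it fails no rule); the order affects only the attribution
#' trace.
#'
#' @param variants Tibble of annotated variants with columns `ref`, `alt`,
#'   `filters`, `region_class`, `exonic_function`, `qual`, `depth`, `vaf`,
#'   `sor` and optional `af_exac`/`af_esp`/`af_1kg` (absent or `NA` treated
#'   as 0).
#' @param cfg A [filter_config()].
#' @return List with `kept` (tibble of retained variants), `trace` (tibble
#'   `rule`, `removed` in rule order), `n_input`, `n_kept`. Conservation:
#'   `n_kept + sum(trace$removed) == n_input`.
#' @export
apply_filter_cascade <- function(variants, cfg = filter_config()) {
  variants <- dplyr::as_tibble(variants)
  if (nrow(variants) == 0) {
    return(list(kept = variants,
                trace = tibble::tibble(rule = cfg$rules, removed = 0L),
                n_input = 0L, n_kept = 0L))
  }
  fails <- rule_failures_(variants, cfg)[, cfg$rules, drop = FALSE]
  first_fail <- apply(fails, 1, function(f) if (any(f)) which(f)[1] else NA_integer_)
  removed_by <- table(factor(cfg$rules[first_fail], levels = cfg$rules))
  kept <- variants[is.na(first_fail), , drop = FALSE]
  list(
    kept = kept,
    trace = tibble::tibble(rule = cfg$rules, removed = as.integer(removed_by)),
    n_input = nrow(variants),
    n_kept = nrow(kept)
  )
}

#' Left-normalize short-variant alleles
#'
#' Trims shared trailing then leading bases of ref/alt (keeping at least
#' one base each, advancing `pos` as leading bases are trimmed) so that
#' equivalent representations key identically.
#'
#' @param pos 0-based positions.
#' @param ref,alt Allele strings.
#' @return Tibble with normalized `pos`, `ref`, `alt`.
#' @export
normalize_alleles <- function(pos, ref, alt) {
  out <- purrr::pmap(list(pos, ref, alt), function(p, r, a) {
    # trim common suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim common prefix
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1
    }
    list(pos = p, ref = r, alt = a)
  })
  tibble::tibble(
    pos = vapply(out, `[[`, numeric(1), "pos"),
    ref = vapply(out, `[[`, character(1), "ref"),
    alt = vapply(out, `[[`, character(1), "alt")
  )
}

variant_keys_ <- function(x) {
  nz <- normalize_alleles(x$pos, x$ref, x$alt)
  unique(paste(x$chrom, nz$pos, nz$ref, nz$alt, sep = ":"))
}

#' Three-way overlap of short-variant sets
#'
#' Variants are keyed by (chrom, pos, ref, alt) after allele
#' left-normalization; the seven Venn regions partition the union.
#'
#' @param a,b,c Variant tibbles with columns `chrom`, `pos`, `ref`, `alt`.
#' @param labels Names for the three sets, in order.
#' @return Tibble with columns `region` (e.g. `"A_only"`, `"AB"`, `"ABC"`)
#'   and `count`.
#' @export
three_way_overlap <- function(a, b, c, labels = c("A", "B", "C")) {
  ka <- variant_keys_(a)
  kb <- variant_keys_(b)
  kc <- variant_keys_(c)
  all_keys <- unique(c(ka, kb, kc))
  in_a <- all_keys %in% ka
  in_b <- all_keys %in% kb
  in_c <- all_keys %in% kc
  region <- dplyr::case_when(
    in_a & in_b & in_c ~ paste0(labels[1], labels[2], labels[3]),
    in_a & in_b ~ paste0(labels[1], labels[2]),
    in_a & in_c ~ paste0(labels[1], labels[3]),
    in_b & in_c ~ paste0(labels[2], labels[3]),
    in_a ~ paste0(labels[1], "_only"),
    in_b ~ paste0(labels[2], "_only"),
    TRUE ~ paste0(labels[3], "_only")
  )
  region_levels <- c(paste0(labels, "_only"),
                     paste0(labels[1], labels[2]), paste0(labels[1], labels[3]),
                     paste0(labels[2], labels[3]),
                     paste0(labels[1], labels[2], labels[3]))
  counts <- table(factor(region, levels = region_levels))
  tibble::tibble(region = region_levels, count = as.integer(counts))
}

#' Driver-gene presence/absence matrix
#'
#' @param variants Tibble of kept variants with columns `sample`,
#'   `dataset`, `gene`.
#' @param genes Gene panel; default the five recurrently mutated MM driver
#'   genes BRAF, KRAS, NRAS, TP53, FAM46C.
#' @param datasets Allowed dataset labels; an unknown label in the input is
#'   an error.
#' @return Wide tibble: one row per (sample, dataset) observed, one 0/1
#'   column per panel gene.
#' @export
driver_gene_matrix <- function(variants, genes = MM_DRIVER_GENES,
                               datasets = SHORT_VARIANT_DATASETS) {
  bad <- setdiff(unique(variants$dataset), datasets)
  if (length(bad) > 0) {
    stop("unknown dataset label(s): ", paste(bad, collapse = ", "))
  }
  base <- tidyr::expand_grid(
    sample = unique(variants$sample),
    dataset = intersect(datasets, unique(variants$dataset))
  )
  hits <- variants |>
    dplyr::filter(.data$gene %in% genes) |>
    dplyr::distinct(.data$sample, .data$dataset, .data$gene) |>
    dplyr::mutate(present = 1L)
  out <- base
  for (gg in genes) {
    gh <- hits[hits$gene == gg, c("sample", "dataset", "present")]
    out <- dplyr::left_join(out, gh, by = c("sample", "dataset"))
    out[[gg]] <- ifelse(is.na(out$present), 0L, 1L)
    out$present <- NULL
  }
  out
}
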