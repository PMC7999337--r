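#' @title Pipeline orchestration and report bundle
#' @description Runs every analysis stage over a configured set of inputs
#'   and writes a deterministic report bundle (TSV + JSON) to an output
#'   directory: per-sample concordance tables, type compositions,
#'   prediction matrices, ROC summaries, hotspot reports, filter traces,
#'   Venn counts and the driver-gene matrix, plus a manifest recording the
#'   seed and a config hash.
#' @name cli_report
NULL

write_json_ <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full comparison pipeline
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{samples}{tibble/data frame with columns `sample`, `vcf_a`,
#'       `vcf_b` (paths to the two platforms' SV VCFs per sample).}
#'     \item{method_a, method_b}{platform labels (default `"WES"`,
#'       `"linked-read"`).}
#'     \item{truth}{path to a truth-table TSV, or a long truth tibble, or
#'       `NULL` (ROC stage skipped with a notice).}
#'     \item{arms}{path to a cytoBand file, or an arm tibble; default the
#'       bundled arm map.}
#'     \item{hotspots}{path to a hotspot catalog TSV or a catalog tibble;
#'       stage skipped when absent.}
#'     \item{variants}{path to an annotated short-variant TSV (columns as
#'       in [apply_filter_cascade()] plus `sample`, `dataset`) or a
#'       tibble; stage skipped when absent.}
#'     \item{match}{a [match_config()] (default defaults).}
#'     \item{filter}{a [filter_config()] (default defaults).}
#'     \item{pass_only}{use PASS calls for cytogenetics/hotspots
#'       (default `TRUE`).}
#'     \item{seed}{integer seed recorded in the manifest and used for the
#'       AUC bootstrap.}
#'     \item{out_dir}{output directory; must not already contain a
#'       manifest unless `overwrite = TRUE`.}
#'   }
#' @param overwrite Overwrite an existing bundle? Default `FALSE`.
#' @return The report bundle (named list of tibbles/values), invisibly.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  cfg <- config
  stopifnot(!is.null(cfg$samples), !is.null(cfg$out_dir))
  method_a <- cfg$method_a %||% "WES"
  method_b <- cfg$method_b %||% "linked-read"
  mcfg <- cfg$match %||% match_config()
  fcfg <- cfg$filter %||% filter_config()
  pass_only <- cfg$pass_only %||% TRUE
  seed <- cfg$seed %||% 1L
  out_dir <- cfg$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("output directory already holds a report bundle (", manifest_path,
         "); use overwrite = TRUE")
  }

  arms <- cfg$arms %||% default_arm_map()
  if (is.character(arms)) arms <- read_arm_map(arms)
  panel <- build_event_panel(arms)

  samples <- dplyr::as_tibble(cfg$samples)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  bundle <- list()

  callsets <- run_stage("read", {
    purrr::pmap(samples, function(sample, vcf_a, vcf_b, ...) {
      list(
        a = pair_breakends(read_sv_vcf(vcf_a, sample = sample, method = method_a)),
        b = pair_breakends(read_sv_vcf(vcf_b, sample = sample, method = method_b))
      )
    })
  })

  bundle$concordance <- run_stage("concord", {
    purrr::map_dfr(callsets, function(cs) {
      match_callsets(cs$a, cs$b, mcfg) |>
        dplyr::mutate(sample = cs$a$sample, method_a = method_a,
                      method_b = method_b, .before = 1)
    })
  })
  readr::write_tsv(bundle$concordance, file.path(out_dir, "concordance.tsv"))

  bundle$composition <- run_stage("composition", {
    purrr::map_dfr(callsets, function(cs) {
      dplyr::bind_rows(
        dplyr::mutate(type_composition(cs$a), sample = cs$a$sample, method = method_a),
        dplyr::mutate(type_composition(cs$b), sample = cs$b$sample, method = method_b)
      )
    })
  })
  readr::write_tsv(bundle$composition, file.path(out_dir, "composition.tsv"))

  bundle$predictions <- run_stage("cyto", {
    build_prediction_matrix(
      c(purrr::map(callsets, "a"), purrr::map(callsets, "b")),
      panel, pass_only = pass_only
    )
  })
  readr::write_tsv(bundle$predictions, file.path(out_dir, "predictions.tsv"))

  truth <- cfg$truth
  if (is.character(truth)) truth <- read_truth_table(truth)
  if (!is.null(truth)) {
    bundle$roc <- run_stage("roc", {
      purrr::map(setNames(c(method_a, method_b), c(method_a, method_b)),
                 function(m) {
        roc_curve(bundle$predictions, truth, method = m, ci = TRUE,
                  n_boot = cfg$n_boot %||% 2000, seed = seed)
      })
    })
    roc_summary <- purrr::imap_dfr(bundle$roc, function(r, m) {
      dplyr::mutate(glance(r), method = m, .before = 1)
    })
    readr::write_tsv(roc_summary, file.path(out_dir, "roc_summary.tsv"))
    write_json_(purrr::map(bundle$roc, function(r) {
      list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high, P = r$P, N = r$N)
    }), file.path(out_dir, "roc.json"))
    purrr::iwalk(bundle$roc, function(r, m) {
      readr::write_tsv(tidy(r), file.path(out_dir, sprintf("roc_curve_%s.tsv", m)))
    })
  } else {
    message("no truth table configured: ROC stage skipped")
  }

  catalog <- cfg$hotspots
  if (is.character(catalog)) catalog <- read_hotspot_catalog(catalog)
  if (!is.null(catalog)) {
    bundle$hotspots <- run_stage("hotspots", {
      all_samples <- samples$sample
      hits_a <- purrr::map_dfr(callsets, ~ annotate_hotspots(.x$a, catalog,
                                                             pass_only = pass_only))
      hits_b <- purrr::map_dfr(callsets, ~ annotate_hotspots(.x$b, catalog,
                                                             pass_only = pass_only))
      counts <- dplyr::bind_rows(
        dplyr::mutate(hotspot_counts(hits_a, all_samples), method = method_a),
        dplyr::mutate(hotspot_counts(hits_b, all_samples), method = method_b)
      )
      list(hits = dplyr::bind_rows(
             dplyr::mutate(hits_a, method = method_a),
             dplyr::mutate(hits_b, method = method_b)),
           counts = counts,
           summary = counts |>
             dplyr::group_by(.data$method) |>
             dplyr::group_modify(~ cohort_summary(.x)) |>
             dplyr::ungroup())
    })
    readr::write_tsv(bundle$hotspots$hits, file.path(out_dir, "hotspot_hits.tsv"))
    readr::write_tsv(bundle$hotspots$counts, file.path(out_dir, "hotspot_counts.tsv"))
    readr::write_tsv(bundle$hotspots$summary, file.path(out_dir, "hotspot_summary.tsv"))
  }

  variants <- cfg$variants
  if (is.character(variants)) {
    variants <- readr::read_tsv(variants, show_col_types = FALSE)
  }
  if (!is.null(variants)) {
    bundle$shortvar <- run_stage("shortvar", {
      res <- apply_filter_cascade(variants, fcfg)
      by_ds <- split(res$kept, res$kept$dataset)
      venn <- if (length(by_ds) == 3) {
        three_way_overlap(by_ds[[1]], by_ds[[2]], by_ds[[3]],
                          labels = names(by_ds))
      } else {
        NULL
      }
      drivers <- driver_gene_matrix(res$kept)
      list(trace = res$trace, n_input = res$n_input, n_kept = res$n_kept,
           venn = venn, drivers = drivers)
    })
    readr::write_tsv(bundle$shortvar$trace, file.path(out_dir, "filter_trace.tsv"))
    if (!is.null(bundle$shortvar$venn)) {
      readr::write_tsv(bundle$shortvar$venn, file.path(out_dir, "venn.tsv"))
    }
    readr::write_tsv(bundle$shortvar$drivers, file.path(out_dir, "driver_matrix.tsv"))
  }

  write_json_(
    list(
      package = "svconcord",
      version = as.character(utils::packageVersion("svconcord")),
      seed = seed,
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
      samples = samples$sample,
      methods = c(method_a, method_b),
      stages = names(bundle)
    ),
    manifest_path
  )
  invisible(bundle)
}
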