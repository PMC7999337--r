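#' @title Synthetic callset and variant generation
#' @description Generates Manta-dialect SV callsets, FISH-style truth
#'   tables and annotated short-variant tables with the statistical
#'   structure the analysis assumes: per-platform SV type compositions,
#'   log-normal size spectra, sub-50 bp candidate fractions, planted
#'   cytogenetic events with configurable per-method detection sensitivity,
#'   and mutually MATEID-paired breakend rows. The genome model is the arm
#'   map itself — calls are placed uniformly within arms; coordinates, not
#'   sequence, drive every downstream computation.
#' @name synthetic
NULL

#' Construct a synthetic callset profile
#'
#' @param name Profile/platform label.
#' @param composition Named numeric vector of proportions over
#'   `DEL`, `DUP`, `INS`, `INV`, `BND`. Renormalized (with a warning) if it
#'   does not sum to 1 within 1e-9.
#' @param size_median Named vector of median SV sizes in bp per type.
#' @param size_sigma Log-normal sigma (log scale) for sizes. Default 1.
#' @param n_calls Expected total number of calls.
#' @param fp_rate Fraction of `n_calls` drawn as background (not derived
#'   from planted truth). Default 1: all bulk calls are background;
#'   truth-supporting calls are added on top.
#' @param sub50_fraction Fraction of background calls shorter than 50 bp.
#' @return An `sv_profile` list.
#' @export
sv_profile <- function(name, composition,
                       size_median = c(DEL = 5000, DUP = 5000, INV = 5000, INS = 100),
                       size_sigma = 1, n_calls = 1000, fp_rate = 1,
                       sub50_fraction = 0.2) {
  stopifnot(all(names(composition) %in% SVTYPES), all(composition >= 0),
            fp_rate >= 0, fp_rate <= 1, sub50_fraction >= 0, sub50_fraction < 1)
  comp <- setNames(rep(0, length(SVTYPES)), SVTYPES)
  comp[names(composition)] <- composition
  s <- sum(comp)
  if (s <= 0) stop("composition must have positive mass")
  if (abs(s - 1) > 1e-9) {
    warning("composition sums to ", format(s), "; renormalizing")
    comp <- comp / s
  }
  structure(
    list(name = name, composition = comp, size_median = size_median,
         size_sigma = size_sigma, n_calls = n_calls, fp_rate = fp_rate,
         sub50_fraction = sub50_fraction),
    class = "sv_profile"
  )
}

#' Default platform profiles
#'
#' `wes_like` follows the WES type composition (DEL 56.3%, INS 32.6%,
#' translocations 6.7%, DUP 3.3%, INV 1.2%; the printed percentages sum to
#' 100.1 and are renormalized). `linkedread_like` is inversion-dominated
#' (92.4% INV) with zero insertions; the residual is split DUP-heavy
#' (DUP 6.6%, DEL 0.3%, BND 0.3%, renormalized).
#'
#' @return Named list of two [sv_profile()] objects.
#' @export
default_profiles <- function() {
  wes <- c(DEL = 0.563, INS = 0.326, BND = 0.067, DUP = 0.033, INV = 0.012)
  lr <- c(INV = 0.924, DUP = 0.066, DEL = 0.003, BND = 0.003, INS = 0)
  list(
    wes_like = sv_profile("wes_like", wes / sum(wes), n_calls = 4065),
    linkedread_like = sv_profile("linkedread_like", lr / sum(lr), n_calls = 18455)
  )
}

#' Simulate a FISH-style truth table
#'
#' Plants panel events per sample as independent Bernoulli draws.
#'
#' @param n_samples Number of samples.
#' @param panel Panel tibble from [build_event_panel()].
#' @param prevalence Per-event planting probability, scalar or named by
#'   `event_id`. Default 0.175 (about 14 positives on an 8-sample,
#'   10-event grid).
#' @param seed Integer seed.
#' @return Long truth tibble (`sample`, `event_id`, `label`).
#' @export
simulate_truth <- function(n_samples, panel, prevalence = 0.175, seed = 1) {
  stopifnot(n_samples >= 1, all(prevalence >= 0), all(prevalence <= 1))
  samples <- sprintf("S%02d", seq_len(n_samples))
  prev <- if (length(prevalence) == 1) {
    setNames(rep(prevalence, nrow(panel)), panel$event_id)
  } else {
    prevalence[panel$event_id]
  }
  withr::with_seed(seed, {
    tidyr::expand_grid(sample = samples, event_id = panel$event_id) |>
      dplyr::mutate(label = rbinom(dplyr::n(), 1, prev[.data$event_id]))
  })
}

# draw an SV size for one type; sub-50 candidates drawn uniformly in 10..49
draw_sizes_ <- function(profile, svtype, n) {
  med <- profile$size_median[[svtype]] %||% 5000
  sz <- round(rlnorm(n, meanlog = log(med), sdlog = profile$size_sigma))
  sz <- pmax(sz, 50)
  sub <- runif(n) < profile$sub50_fraction
  sz[sub] <- sample(10:49, sum(sub), replace = TRUE)
  sz
}

# uniform placement of an interval of length size within [lo, hi)
place_interval_ <- function(lo, hi, size) {
  size <- pmin(size, hi - lo - 1)
  start <- floor(runif(length(size), lo, hi - size))
  tibble::tibble(start = as.integer(start), end = as.integer(start + size))
}

chrom_spans_ <- function(arms) {
  arms |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop")
}

#' Generate a synthetic Manta-dialect callset
#'
#' Emits one supporting call per planted panel event with probability
#' `sensitivity` (a deletion/duplication placed inside the event arm, or a
#' mutually MATEID-paired breakend pair joining the event chromosomes),
#' plus background calls drawn from the profile's type composition and
#' size distributions at uniform placements within arms. All generated
#' records carry FILTER PASS. The result round-trips through
#' [write_sv_vcf()], [read_sv_vcf()] and [pair_breakends()] without loss.
#'
#' @param profile An [sv_profile()].
#' @param sample Sample identifier.
#' @param truth Long truth tibble (as from [simulate_truth()]); only this
#'   sample's rows are used. `NULL` for background-only callsets.
#' @param panel Panel tibble; required when `truth` is given.
#' @param sensitivity Probability that a planted event emits a supporting
#'   call; scalar or named by event kind (`arm_loss`, `arm_gain`,
#'   `translocation`).
#' @param arms Arm map tibble. Default [default_arm_map()].
#' @param n_calls Override the profile's expected call count.
#' @param seed Integer seed; the same seed reproduces the callset exactly.
#' @param method Platform label. Defaults to the profile name.
#' @param vcf_path If non-`NULL`, also write the callset as a VCF here.
#' @return An [sv_callset()] (breakends unpaired, as read from a VCF).
#' @export
generate_callset <- function(profile, sample, truth = NULL, panel = NULL,
                             sensitivity = 1, arms = default_arm_map(),
                             n_calls = NULL, seed = 1,
                             method = profile$name, vcf_path = NULL) {
  stopifnot(inherits(profile, "sv_profile"))
  n_calls <- n_calls %||% profile$n_calls
  spans <- chrom_spans_(arms)
  withr::with_seed(seed, {
    rows <- list()
    rid <- 0
    next_id <- function(type) {
      rid <<- rid + 1
      sprintf("%s_%s_%05d", method, type, rid)
    }
    add_interval <- function(svtype, chrom, start, end) {
      len <- end - start
      rows[[length(rows) + 1]] <<- tibble::tibble(
        record_id = next_id(svtype), svtype = svtype, chrom = chrom,
        start = as.integer(start), end = as.integer(end),
        svlen = ifelse(svtype == "DEL", -len, len),
        qual = round(runif(1, 20, 999)), filter = "PASS",
        mate_id = NA_character_, mate_chrom = NA_character_,
        mate_pos = NA_integer_, orientation = NA_character_,
        is_sub50 = abs(len) < 50
      )
    }
    add_bnd_pair <- function(chrom1, pos1, chrom2, pos2) {
      base <- next_id("BND")
      id1 <- paste0(base, ":0")
      id2 <- paste0(base, ":1")
      q <- round(runif(1, 20, 999))
      rows[[length(rows) + 1]] <<- tibble::tibble(
        record_id = c(id1, id2), svtype = "BND",
        chrom = c(chrom1, chrom2), start = as.integer(c(pos1, pos2)),
        end = NA_integer_, svlen = NA_real_, qual = q, filter = "PASS",
        mate_id = c(id2, id1), mate_chrom = c(chrom2, chrom1),
        mate_pos = as.integer(c(pos2, pos1)),
        orientation = c("t[p[", "]p]t"), is_sub50 = FALSE
      )
    }
    rand_pos <- function(chrom) {
      sp <- spans[spans$chrom == chrom, ]
      as.integer(floor(runif(1, sp$lo, sp$hi)))
    }

    # planted event-supporting calls
    if (!is.null(truth)) {
      if (is.null(panel)) stop("panel required when truth is supplied")
      planted <- dplyr::inner_join(
        truth[truth$sample == sample & truth$label == 1L, , drop = FALSE],
        panel, by = "event_id"
      )
      for (i in seq_len(nrow(planted))) {
        ev <- planted[i, ]
        s <- if (length(sensitivity) == 1) sensitivity else sensitivity[[ev$kind]]
        if (runif(1) > s) next
        if (ev$kind == "translocation") {
          chroms <- strsplit(ev$chrom_pair, ":", fixed = TRUE)[[1]]
          add_bnd_pair(chroms[1], rand_pos(chroms[1]), chroms[2], rand_pos(chroms[2]))
        } else {
          svtype <- if (ev$kind == "arm_loss") "DEL" else "DUP"
          size <- draw_sizes_(profile, svtype, 1)
          iv <- place_interval_(ev$start, ev$end, pmax(size, 50))
          add_interval(svtype, ev$chrom, iv$start, iv$end)
        }
      }
    }

    # background calls from the composition (bulk-generated per type)
    n_bg <- round(n_calls * profile$fp_rate)
    if (n_bg > 0) {
      types <- sample(SVTYPES, n_bg, replace = TRUE, prob = profile$composition)
      bg_chrom <- sample(spans$chrom, n_bg, replace = TRUE,
                         prob = spans$hi - spans$lo)
      lo <- spans$lo[match(bg_chrom, spans$chrom)]
      hi <- spans$hi[match(bg_chrom, spans$chrom)]
      for (tt in c("DEL", "DUP", "INV", "INS")) {
        k <- which(types == tt)
        if (length(k) == 0) next
        if (tt == "INS") {
          pos <- as.integer(floor(runif(length(k), lo[k], hi[k])))
          len <- draw_sizes_(profile, "INS", length(k))
          rows[[length(rows) + 1]] <- tibble::tibble(
            record_id = sprintf("%s_INS_b%05d", method, seq_along(k)),
            svtype = "INS", chrom = bg_chrom[k],
            start = pos, end = pos + 1L, svlen = as.numeric(len),
            qual = round(runif(length(k), 20, 999)), filter = "PASS",
            mate_id = NA_character_, mate_chrom = NA_character_,
            mate_pos = NA_integer_, orientation = NA_character_,
            is_sub50 = len < 50
          )
        } else {
          size <- draw_sizes_(profile, tt, length(k))
          iv <- place_interval_(lo[k], hi[k], size)
          len <- iv$end - iv$start
          rows[[length(rows) + 1]] <- tibble::tibble(
            record_id = sprintf("%s_%s_b%05d", method, tt, seq_along(k)),
            svtype = tt, chrom = bg_chrom[k],
            start = iv$start, end = iv$end,
            svlen = if (tt == "DEL") -len else len,
            qual = round(runif(length(k), 20, 999)), filter = "PASS",
            mate_id = NA_character_, mate_chrom = NA_character_,
            mate_pos = NA_integer_, orientation = NA_character_,
            is_sub50 = len < 50
          )
        }
      }
      kb <- which(types == "BND")
      if (length(kb) > 0) {
        chrom2 <- vapply(bg_chrom[kb], function(ch) {
          sample(setdiff(spans$chrom, ch), 1)
        }, character(1))
        pos1 <- as.integer(floor(runif(length(kb), lo[kb], hi[kb])))
        lo2 <- spans$lo[match(chrom2, spans$chrom)]
        hi2 <- spans$hi[match(chrom2, spans$chrom)]
        pos2 <- as.integer(floor(runif(length(kb), lo2, hi2)))
        id1 <- sprintf("%s_BND_b%05d:0", method, seq_along(kb))
        id2 <- sprintf("%s_BND_b%05d:1", method, seq_along(kb))
        q <- round(runif(length(kb), 20, 999))
        rows[[length(rows) + 1]] <- tibble::tibble(
          record_id = c(id1, id2), svtype = "BND",
          chrom = c(bg_chrom[kb], chrom2),
          start = c(pos1, pos2), end = NA_integer_,
          svlen = NA_real_, qual = c(q, q), filter = "PASS",
          mate_id = c(id2, id1), mate_chrom = c(chrom2, bg_chrom[kb]),
          mate_pos = c(pos2, pos1),
          orientation = rep(c("t[p[", "]p]t"), each = length(kb)),
          is_sub50 = FALSE
        )
      }
    }

    records <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_sv_records()
    cs <- sv_callset(records, sample, method)
    if (!is.null(vcf_path)) write_sv_vcf(cs, vcf_path, arms = arms)
    cs
  })
}

#' Write a callset as a Manta-dialect VCF
#'
#' Interval records are written with 1-based `POS = start + 1` and INFO
#' `END = end` (so the stored 0-based half-open interval and `|SVLEN|`
#' round-trip exactly); breakend pairs are written as two BND rows with
#' bracketed ALT notation and mutual `MATEID`.
#'
#' @param callset An [sv_callset()].
#' @param path Output VCF path (plain text).
#' @param arms Optional arm map used to emit `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(callset, path, arms = NULL) {
  r <- callset$records
  header <- c(
    "##fileformat=VCFv4.1",
    "##source=svconcord-synthetic",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Signed difference in length\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"ID of mate breakend\">",
    "##FILTER=<ID=MinQUAL,Description=\"QUAL below threshold\">"
  )
  if (!is.null(arms)) {
    sp <- chrom_spans_(arms)
    header <- c(header,
                sprintf("##contig=<ID=%s,length=%d>", sp$chrom, sp$hi))
  }
  header <- c(header,
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                    sep = "\t"))
  body <- character(0)
  if (nrow(r) > 0) {
    is_bnd <- r$svtype == "BND"
    info <- character(nrow(r))
    alt <- character(nrow(r))
    pos1 <- r$start + 1L
    for (i in seq_len(nrow(r))) {
      if (is_bnd[i]) {
        mp <- r$mate_pos[i] + 1L
        alt[i] <- switch(r$orientation[i],
          "t[p[" = sprintf("N[%s:%d[", r$mate_chrom[i], mp),
          "t]p]" = sprintf("N]%s:%d]", r$mate_chrom[i], mp),
          "]p]t" = sprintf("]%s:%d]N", r$mate_chrom[i], mp),
          "[p[t" = sprintf("[%s:%d[N", r$mate_chrom[i], mp)
        )
        info[i] <- sprintf("SVTYPE=BND;MATEID=%s", r$mate_id[i])
      } else {
        alt[i] <- sprintf("<%s>", r$svtype[i])
        info[i] <- sprintf("SVTYPE=%s;END=%d", r$svtype[i], r$end[i])
        if (!is.na(r$svlen[i])) {
          info[i] <- sprintf("%s;SVLEN=%d", info[i], as.integer(r$svlen[i]))
        }
      }
    }
    ord <- order(r$chrom, pos1)
    body <- sprintf("%s\t%d\t%s\tN\t%s\t%s\t%s\t%s",
                    r$chrom, pos1, r$record_id, alt,
                    ifelse(is.na(r$qual), ".", format(r$qual, trim = TRUE)),
                    r$filter, info)[ord]
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate an annotated short-variant table
#'
#' Each variant is engineered to pass every cascade rule or to fail exactly
#' one designated rule, drawn with the given probabilities; the expected
#' kept fraction is `1 - sum(fail_fractions)`. The planted failure is
#' recorded in `planted_rule` (`"pass"` for clean variants), which the
#' cascade itself never reads.
#'
#' @param n Number of variants.
#' @param fail_fractions Named numeric vector over the cascade rules
#'   (subset of `r toString(FILTER_RULES)`); must sum to <= 1.
#' @param sample,dataset Labels attached to every row.
#' @param seed Integer seed.
#' @return Tibble of annotated variants.
#' @export
generate_short_variants <- function(n, fail_fractions = c(), sample = "S01",
                                    dataset = "WES", seed = 1) {
  if (length(fail_fractions) > 0) {
    stopifnot(all(names(fail_fractions) %in% FILTER_RULES),
              sum(fail_fractions) <= 1, all(fail_fractions >= 0))
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    p_pass <- 1 - sum(fail_fractions)
    planted <- sample(c("pass", names(fail_fractions)), n, replace = TRUE,
                      prob = c(p_pass, unname(fail_fractions)))
    vclass <- sample(c("SNV", "insertion", "deletion"), n, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(seq_len(n), function(i) {
      if (vclass[i] == "SNV") sample(setdiff(bases, ref[i]), 1)
      else if (vclass[i] == "insertion") {
        paste0(ref[i], paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = ""))
      } else ref[i]
    }, character(1))
    ref <- ifelse(vclass == "deletion",
                  paste0(ref, vapply(seq_len(n), function(i) {
                    paste(sample(bases, sample(1:5, 1), replace = TRUE), collapse = "")
                  }, character(1))),
                  ref)
    v <- tibble::tibble(
      sample = sample, dataset = dataset,
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n, replace = TRUE),
      ref = ref, alt = alt, variant_class = vclass,
      region_class = "exonic", exonic_function = "nonsynonymous",
      af_exac = runif(n, 0, 0.005), af_esp = runif(n, 0, 0.005),
      af_1kg = runif(n, 0, 0.005),
      qual = runif(n, 50, 250), depth = 10 + rpois(n, 90),
      vaf = runif(n, 0.05, 0.25), sor = runif(n, 0.1, 2),
      gene = sample(c(MM_DRIVER_GENES, "TTN", "MUC16", "OBSCN"), n, replace = TRUE),
      filters = "PASS",
      planted_rule = planted
    )
    # engineer the single designated failure per variant
    i <- which(planted == "caller_filter")
    v$filters[i] <- "clustered_events"
    i <- which(planted == "region")
    v$region_class[i] <- sample(c("intronic", "intergenic"), length(i), replace = TRUE)
    i <- which(planted == "exonic_function")
    v$exonic_function[i] <- sample(c("synonymous", "nonframeshift"), length(i),
                                   replace = TRUE)
    i <- which(planted == "pop_af")
    v$af_1kg[i] <- runif(length(i), 0.02, 0.5)
    i <- which(planted == "qual")
    v$qual[i] <- runif(length(i), 0, 39.5)
    i <- which(planted == "depth")
    v$depth[i] <- sample(0:9, length(i), replace = TRUE)
    i <- which(planted == "vaf")
    v$vaf[i] <- ifelse(runif(length(i)) < 0.5,
                       runif(length(i), 0.001, 0.019), runif(length(i), 0.31, 0.9))
    i <- which(planted == "sor")
    v$sor[i] <- ifelse(v$variant_class[i] == "SNV",
                       runif(length(i), 3.1, 10), runif(length(i), 11.1, 25))
    v
  })
}

#' Generate a two-platform synthetic cohort
#'
#' Simulates a truth table and, for every sample, one callset per platform
#' profile with platform-specific detection sensitivity — the harness for
#' end-to-end concordance, cytogenetics and ROC evaluation.
#'
#' @param n_samples Number of samples. Default 8.
#' @param profiles Named list of [sv_profile()] objects. Default
#'   [default_profiles()].
#' @param sensitivities Named vector of planted-event detection
#'   sensitivities, one per profile.
#' @param prevalence Event prevalence for [simulate_truth()].
#' @param arms Arm map.
#' @param panel Event panel; default built from `arms`.
#' @param n_calls Optional named vector overriding each profile's
#'   background call count.
#' @param seed Integer seed.
#' @param dir If non-`NULL`, VCFs (one per sample and platform) and the
#'   truth TSV are written here.
#' @return List with `truth` (long tibble), `callsets` (named list of
#'   lists of [sv_callset()] per profile) and `paths` (when `dir` given).
#' @export
generate_cohort <- function(n_samples = 8, profiles = default_profiles(),
                            sensitivities = c(wes_like = 0.9, linkedread_like = 0.5),
                            prevalence = 0.175, arms = default_arm_map(),
                            panel = build_event_panel(arms), n_calls = NULL,
                            seed = 1, dir = NULL) {
  truth <- simulate_truth(n_samples, panel, prevalence, seed = seed)
  samples <- unique(truth$sample)
  paths <- list()
  callsets <- purrr::imap(profiles, function(profile, pname) {
    purrr::map(seq_along(samples), function(i) {
      smp <- samples[i]
      vcf <- NULL
      if (!is.null(dir)) {
        vcf <- file.path(dir, sprintf("%s_%s.vcf", smp, pname))
        paths[[paste(smp, pname)]] <<- vcf
      }
      generate_callset(
        profile, sample = smp, truth = truth, panel = panel,
        sensitivity = sensitivities[[pname]], arms = arms,
        n_calls = if (!is.null(n_calls)) n_calls[[pname]] else NULL,
        seed = seed + 7919L * i + 104729L * match(pname, names(profiles)),
        vcf_path = vcf
      )
    })
  })
  if (!is.null(dir)) {
    truth_path <- file.path(dir, "truth.tsv")
    readr::write_tsv(prediction_matrix_wide(truth, value = "label"), truth_path)
    paths$truth <- truth_path
  }
  list(truth = truth, callsets = callsets, paths = paths)
}
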