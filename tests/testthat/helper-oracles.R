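# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package: exhaustive all-pairs
# enumeration and direct arithmetic only.

# random interval/INS record table on a small artificial genome
random_records <- function(n, chroms = as.character(1:5), span = 1e6,
                           types = c("DEL", "DUP", "INV", "INS")) {
  svtype <- sample(types, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE)
  len <- pmax(50, round(rlnorm(n, log(5000), 1)))
  end <- ifelse(svtype == "INS", start + 1L, start + len)
  tibble::tibble(
    record_id = sprintf("r%04d", seq_len(n)), svtype = svtype,
    chrom = sample(chroms, n, replace = TRUE),
    start = as.integer(start), end = as.integer(end),
    svlen = ifelse(svtype == "DEL", -len, len),
    qual = 100, filter = "PASS",
    mate_id = NA_character_, mate_chrom = NA_character_,
    mate_pos = NA_integer_, orientation = NA_character_,
    is_sub50 = FALSE
  )
}

# exhaustive all-pairs matcher over interval/INS records
oracle_match <- function(ra, rb, frac, reciprocal = TRUE, ins_window = 50) {
  types <- c("DEL", "DUP", "INS", "INV")
  out <- lapply(types, function(tt) {
    A <- ra[ra$svtype == tt, , drop = FALSE]
    B <- rb[rb$svtype == tt, , drop = FALSE]
    hit_a <- logical(nrow(A))
    hit_b <- logical(nrow(B))
    if (nrow(A) > 0 && nrow(B) > 0) {
      for (i in seq_len(nrow(A))) {
        same <- B$chrom == A$chrom[i]
        if (tt == "INS") {
          ok <- same & abs(B$start - A$start[i]) <= ins_window
        } else {
          ov <- pmax(0, pmin(B$end, A$end[i]) - pmax(B$start, A$start[i]))
          fa <- ov / (A$end[i] - A$start[i])
          fb <- ov / (B$end - B$start)
          ok <- same & (if (reciprocal) fa >= frac & fb >= frac else fa >= frac)
        }
        if (any(ok)) {
          hit_a[i] <- TRUE
          hit_b[ok] <- TRUE
        }
      }
    }
    data.frame(svtype = tt, n_a = nrow(A), n_b = nrow(B),
               shared = sum(hit_a), a_only = sum(!hit_a), b_only = sum(!hit_b))
  })
  out <- do.call(rbind, out)
  tibble::as_tibble(out[order(match(out$svtype, c("DEL", "DUP", "INS", "INV"))), ])
}

# Mann-Whitney concordance probability by exhaustive pair enumeration
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  mean(wins + 0.5 * ties)
}

# brute-force mutual-MATEID pairing: count of unordered reciprocal pairs
oracle_bnd_pairs <- function(recs) {
  bnd <- recs[recs$svtype == "BND", , drop = FALSE]
  n_pairs <- 0L
  paired <- character(0)
  if (nrow(bnd) >= 2) {
    for (i in seq_len(nrow(bnd) - 1)) {
      for (j in (i + 1):nrow(bnd)) {
        if (!is.na(bnd$mate_id[i]) && !is.na(bnd$mate_id[j]) &&
            bnd$mate_id[i] == bnd$record_id[j] &&
            bnd$mate_id[j] == bnd$record_id[i]) {
          n_pairs <- n_pairs + 1L
          paired <- c(paired, bnd$record_id[i], bnd$record_id[j])
        }
      }
    }
  }
  list(n_pairs = n_pairs, unpaired = setdiff(bnd$record_id, paired))
}

# brute-force per-record panel classification
oracle_detect <- function(records, translocations, panel) {
  score <- setNames(integer(nrow(panel)), panel$event_id)
  for (e in seq_len(nrow(panel))) {
    ev <- panel[e, ]
    if (ev$kind == "translocation") {
      for (t in seq_len(nrow(translocations))) {
        tr <- translocations[t, ]
        pair <- paste(sort(c(tr$chrom_a, tr$chrom_b)), collapse = ":")
        if (tr$chrom_a != tr$chrom_b && pair == ev$chrom_pair && tr$pass) {
          score[e] <- score[e] + 1L
        }
      }
    } else {
      want <- if (ev$kind == "arm_loss") "DEL" else "DUP"
      for (r in seq_len(nrow(records))) {
        rec <- records[r, ]
        if (rec$svtype == want && rec$filter == "PASS" &&
            rec$chrom == ev$chrom &&
            min(rec$end, ev$end) > max(rec$start, ev$start)) {
          score[e] <- score[e] + 1L
        }
      }
    }
  }
  score
}

# brute-force breakpoint-containment hotspot hits: sample x hotspot pairs
oracle_hotspot_ids <- function(records, translocations, catalog) {
  hit <- character(0)
  contains <- function(h, chrom, p) {
    h$chrom == chrom && p >= h$start && p < h$end
  }
  for (k in seq_len(nrow(catalog))) {
    h <- catalog[k, ]
    found <- FALSE
    for (r in seq_len(nrow(records))) {
      rec <- records[r, ]
      if (rec$svtype == "BND" || rec$filter != "PASS") next
      if (contains(h, rec$chrom, rec$start) ||
          contains(h, rec$chrom, rec$end - 1)) {
        found <- TRUE
      }
    }
    if (nrow(translocations) > 0) {
      for (t in seq_len(nrow(translocations))) {
        tr <- translocations[t, ]
        if (!tr$pass) next
        if (contains(h, tr$chrom_a, tr$pos_a) ||
            contains(h, tr$chrom_b, tr$pos_b)) {
          found <- TRUE
        }
      }
    }
    if (found) hit <- c(hit, h$hotspot_id)
  }
  sort(hit)
}

# build an sv_callset straight from a record table
make_callset <- function(records, sample = "S01", method = "WES") {
  sv_callset(records, sample = sample, method = method)
}

# a small arm map with simple round coordinates for hand-checked fixtures
toy_arms <- function() {
  path <- tempfile(fileext = ".tsv")
  lines <- c()
  for (ch in c("1", "4", "6", "11", "13", "14", "16", "17", "20")) {
    lines <- c(lines,
               sprintf("chr%s\t0\t1000000\tp11\tgneg", ch),
               sprintf("chr%s\t1000000\t2000000\tq11\tgneg", ch))
  }
  writeLines(lines, path)
  read_arm_map(path)
}
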