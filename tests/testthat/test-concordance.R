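interval_cs <- function(specs, sample = "S01", method = "WES") {
  # specs: list of c(svtype, chrom, start, end)
  recs <- purrr::imap_dfr(specs, function(s, i) {
    len <- as.integer(s[[4]]) - as.integer(s[[3]])
    tibble::tibble(
      record_id = sprintf("%s_r%03d", method, i), svtype = s[[1]],
      chrom = s[[2]], start = as.integer(s[[3]]), end = as.integer(s[[4]]),
      svlen = ifelse(s[[1]] == "DEL", -len, len), qual = 99, filter = "PASS",
      mate_id = NA_character_, mate_chrom = NA_character_,
      mate_pos = NA_integer_, orientation = NA_character_, is_sub50 = FALSE
    )
  })
  make_callset(recs, sample, method)
}

test_that("reciprocal overlap fractions follow interval arithmetic", {
  expect_equal(reciprocal_overlap("1", 100, 200, "1", 100, 200),
               tibble::tibble(frac_a = 1, frac_b = 1))
  expect_equal(reciprocal_overlap("1", 100, 200, "1", 150, 250),
               tibble::tibble(frac_a = 0.5, frac_b = 0.5))
  expect_equal(reciprocal_overlap("1", 100, 200, "1", 300, 400),
               tibble::tibble(frac_a = 0, frac_b = 0))
  expect_equal(reciprocal_overlap("1", 100, 200, "2", 100, 200),
               tibble::tibble(frac_a = 0, frac_b = 0))
  # symmetric under swap with components exchanged
  f1 <- reciprocal_overlap("1", 100, 200, "1", 150, 400)
  f2 <- reciprocal_overlap("1", 150, 400, "1", 100, 200)
  expect_equal(f1$frac_a, f2$frac_b)
  expect_equal(f1$frac_b, f2$frac_a)
})

test_that("a 50% overlap fails the default 70% rule but passes F=0.5", {
  a <- interval_cs(list(c("DEL", "1", 100, 200)))
  b <- interval_cs(list(c("DEL", "1", 150, 250)), method = "LR")
  t70 <- match_callsets(a, b)
  expect_equal(t70$shared[t70$svtype == "DEL"], 0)
  t50 <- match_callsets(a, b, match_config(fraction = 0.5))
  expect_equal(t50$shared[t50$svtype == "DEL"], 1)
})

test_that("self-comparison shares every interval record and type stratification holds", {
  a <- interval_cs(list(
    c("DEL", "1", 100, 5000), c("DUP", "2", 1000, 9000),
    c("INV", "3", 10, 600), c("DEL", "1", 20000, 30000)
  ))
  self <- match_callsets(a, a)
  iv <- self[self$svtype != "BND", ]
  expect_equal(iv$a_only, rep(0L, 4))
  expect_equal(iv$shared, iv$n_a)
  # same span, different type: never shared under type stratification
  b <- interval_cs(list(c("DUP", "1", 0, 100)), method = "LR")
  a2 <- interval_cs(list(c("DEL", "1", 0, 100)))
  tab <- match_callsets(a2, b)
  expect_equal(sum(tab$shared), 0)
  # but shared when stratification is off
  tab2 <- match_callsets(a2, b, match_config(require_same_type = FALSE))
  expect_equal(tab2$shared[tab2$svtype == "DEL"], 1)
})

test_that("mismatched samples error unless overridden", {
  a <- interval_cs(list(c("DEL", "1", 0, 100)), sample = "S01")
  b <- interval_cs(list(c("DEL", "1", 0, 100)), sample = "S02", method = "LR")
  expect_error(match_callsets(a, b), "different samples")
  tab <- match_callsets(a, b, allow_sample_mismatch = TRUE)
  expect_equal(tab$shared[tab$svtype == "DEL"], 1)
})

test_that("match_callsets equals the brute-force matcher on random instances", {
  set.seed(42)
  for (trial in 1:25) {
    frac <- sample(c(0.5, 0.7, 0.9), 1)
    ra <- random_records(sample(20:120, 1))
    rb <- random_records(sample(20:120, 1))
    cfg <- match_config(fraction = frac)
    got <- match_callsets(make_callset(ra), make_callset(rb, method = "LR"),
                          cfg, allow_sample_mismatch = TRUE)
    want <- oracle_match(ra, rb, frac)
    expect_equal(got[got$svtype != "BND", ], want, ignore_attr = TRUE)
  }
})

test_that("shared counts are non-increasing in the overlap fraction", {
  set.seed(99)
  ra <- random_records(150)
  rb <- random_records(150)
  a <- make_callset(ra)
  b <- make_callset(rb, method = "LR")
  shared <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), function(f) {
    sum(match_callsets(a, b, match_config(fraction = f),
                       allow_sample_mismatch = TRUE)$shared)
  }, numeric(1))
  expect_true(all(diff(shared) <= 0))
})

tra_cs <- function(events, sample = "S01", method = "WES") {
  # events: list of c(chrom_a, pos_a, chrom_b, pos_b)
  recs <- purrr::imap_dfr(events, function(e, i) {
    ids <- sprintf("%s_t%02d:%d", method, i, 0:1)
    tibble::tibble(
      record_id = ids, svtype = "BND",
      chrom = c(e[[1]], e[[3]]),
      start = as.integer(c(e[[2]], e[[4]])), end = NA_integer_,
      svlen = NA_real_, qual = 60, filter = "PASS",
      mate_id = rev(ids), mate_chrom = c(e[[3]], e[[1]]),
      mate_pos = as.integer(c(e[[4]], e[[2]])),
      orientation = c("t[p[", "]p]t"), is_sub50 = FALSE
    )
  })
  pair_breakends(make_callset(recs, sample, method))
}

test_that("translocations match by chromosome pair within the breakend window", {
  a <- tra_cs(list(c("14", 1000, "4", 5000)))
  # identical event matches at any window including 0
  expect_equal(
    match_translocations(a, a, match_config(translocation_window = 0))$shared, 1)
  # different partner chromosome never matches
  b <- tra_cs(list(c("14", 1000, "11", 5000)), method = "LR")
  expect_equal(match_translocations(a, b)$shared, 0)
  # displacement exactly W matches; W+1 does not
  w <- 10000
  b2 <- tra_cs(list(c("14", 1000 + w, "4", 5000)), method = "LR")
  expect_equal(match_translocations(a, b2)$shared, 1)
  b3 <- tra_cs(list(c("14", 1000 + w + 1, "4", 5000)), method = "LR")
  expect_equal(match_translocations(a, b3)$shared, 0)
  # reversed breakend order still corresponds by chromosome
  b4 <- tra_cs(list(c("4", 5000, "14", 1000)), method = "LR")
  expect_equal(match_translocations(a, b4)$shared, 1)
})

test_that("type composition is exact arithmetic over feature counts", {
  specs <- c(
    replicate(56, c("DEL", "1", 0, 100), simplify = FALSE),
    replicate(33, c("INS", "1", 0, 1), simplify = FALSE),
    replicate(3, c("DUP", "1", 0, 100), simplify = FALSE),
    replicate(1, c("INV", "1", 0, 100), simplify = FALSE)
  )
  cs <- interval_cs(specs)
  # add 7 translocation events (14 BND records)
  tra <- tra_cs(replicate(7, c("14", 100, "4", 200), simplify = FALSE))
  cs$records <- dplyr::bind_rows(cs$records, tra$records)
  comp <- type_composition(cs)
  expect_equal(comp$proportion[comp$svtype == "DEL"], 0.56)
  expect_equal(comp$proportion[comp$svtype == "INS"], 0.33)
  expect_equal(comp$proportion[comp$svtype == "BND"], 0.07)
  expect_equal(comp$proportion[comp$svtype == "DUP"], 0.03)
  expect_equal(comp$proportion[comp$svtype == "INV"], 0.01)
  expect_equal(sum(comp$proportion), 1, tolerance = 1e-12)
  # single-type callset
  one <- interval_cs(list(c("DEL", "1", 0, 100)))
  expect_equal(type_composition(one)$proportion[1], 1)
  # empty callset errors
  expect_error(type_composition(make_callset(random_records(0))), "empty")
})
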