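write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.1",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##INFO=<ID=SVLEN,Number=.,Type=Integer,Description=\"Length\">",
    "##INFO=<ID=MATEID,Number=.,Type=String,Description=\"Mate\">",
    "##contig=<ID=1,length=10000000>",
    "##contig=<ID=2,length=10000000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t")
  )
  writeLines(c(header, lines), path)
  path
}

test_that("VCF coordinates convert to 0-based half-open intervals", {
  p <- write_test_vcf(c(
    "1\t100\tdel1\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=200;SVLEN=-101",
    "1\t500\tins1\tN\t<INS>\t40\tMinQUAL\tSVTYPE=INS;END=500;SVLEN=120",
    "2\t900\tdel2\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=929;SVLEN=-30"
  ))
  cs <- read_sv_vcf(p, "S01", "WES")
  r <- cs$records
  expect_equal(r$start[r$record_id == "del1"], 99)
  expect_equal(r$end[r$record_id == "del1"], 200)
  # interval length equals |SVLEN| for span types
  expect_equal(r$end[r$svtype == "DEL"] - r$start[r$svtype == "DEL"],
               abs(r$svlen[r$svtype == "DEL"]))
  # sub-50 candidates retained and flagged
  expect_true(r$is_sub50[r$record_id == "del2"])
  expect_false(r$is_sub50[r$record_id == "del1"])
  # non-PASS records retained with their filter string
  expect_equal(r$filter[r$record_id == "ins1"], "MinQUAL")
})

test_that("records without SVTYPE raise a parse error with the line number", {
  p <- write_test_vcf(c(
    "1\t100\tok\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=200",
    "1\t300\tbad\tN\t<DEL>\t60\tPASS\tEND=400"
  ))
  expect_error(read_sv_vcf(p, "S01", "WES"), "SVTYPE.*2")
})

test_that("malformed BND ALT errors name the record", {
  p <- write_test_vcf(
    "1\t100\tbnd_bad\tN\tN[nonsense\t60\tPASS\tSVTYPE=BND;MATEID=x"
  )
  expect_error(read_sv_vcf(p, "S01", "WES"), "bnd_bad")
})

test_that("BND ALT bracket classes parse to mate coordinates", {
  p <- write_test_vcf(c(
    "1\t100\tb1\tN\tN[2:501[\t60\tPASS\tSVTYPE=BND;MATEID=b2",
    "2\t501\tb2\tN\t]1:100]N\t60\tPASS\tSVTYPE=BND;MATEID=b1"
  ))
  cs <- read_sv_vcf(p, "S01", "WES")
  b1 <- cs$records[cs$records$record_id == "b1", ]
  expect_equal(b1$mate_chrom, "2")
  expect_equal(b1$mate_pos, 500)      # 0-based
  expect_equal(b1$orientation, "t[p[")
  expect_equal(cs$records$orientation[cs$records$record_id == "b2"], "]p]t")
})

test_that("chromosome names are normalized by the prefix policy", {
  p <- write_test_vcf(
    "1\t100\td\tN\t<DEL>\t60\tPASS\tSVTYPE=DEL;END=200"
  )
  expect_equal(read_sv_vcf(p, "S", "M")$records$chrom, "1")
  expect_equal(normalize_chrom(c("chr1", "chrX", "2")), c("1", "X", "2"))
  expect_equal(normalize_chrom("chr1", strip_chr = FALSE), "chr1")
})

make_bnd <- function(id, mate, chrom = "1", pos = 100) {
  tibble::tibble(
    record_id = id, svtype = "BND", chrom = chrom, start = pos,
    end = NA_integer_, svlen = NA_real_, qual = 50, filter = "PASS",
    mate_id = mate, mate_chrom = "2", mate_pos = 200L,
    orientation = "t[p[", is_sub50 = FALSE
  )
}

test_that("mutual MATEID pairs collapse to one event; dangling mates are kept unpaired", {
  cs <- make_callset(dplyr::bind_rows(
    make_bnd("a", "b"), make_bnd("b", "a", chrom = "2", pos = 200),
    make_bnd("lone", "ghost")
  ))
  paired <- pair_breakends(cs)
  expect_equal(nrow(paired$translocations), 1)
  expect_equal(nrow(paired$unpaired), 1)
  expect_equal(paired$unpaired$record_id, "lone")
  # every BND accounted for exactly once
  expect_setequal(
    c(paired$translocations$id_a, paired$translocations$id_b,
      paired$unpaired$record_id),
    c("a", "b", "lone")
  )
})

test_that("breakend pairing is permutation-invariant, idempotent and matches brute force", {
  set.seed(11)
  for (trial in 1:20) {
    n_pairs <- sample(0:10, 1)
    n_dangling <- sample(0:4, 1)
    recs <- list()
    for (k in seq_len(n_pairs)) {
      recs[[length(recs) + 1]] <- make_bnd(sprintf("p%da", k), sprintf("p%db", k))
      recs[[length(recs) + 1]] <- make_bnd(sprintf("p%db", k), sprintf("p%da", k),
                                           chrom = "2", pos = 200 + k)
    }
    for (k in seq_len(n_dangling)) {
      recs[[length(recs) + 1]] <- make_bnd(sprintf("d%d", k), sprintf("missing%d", k))
    }
    recs <- dplyr::bind_rows(recs)
    if (nrow(recs) == 0) next
    shuffled <- recs[sample.int(nrow(recs)), ]
    oracle <- oracle_bnd_pairs(shuffled)
    paired <- pair_breakends(make_callset(shuffled))
    expect_equal(nrow(paired$translocations), oracle$n_pairs)
    expect_setequal(paired$unpaired$record_id, oracle$unpaired)
    # idempotent
    again <- pair_breakends(paired)
    expect_equal(nrow(again$translocations), nrow(paired$translocations))
    expect_setequal(again$unpaired$record_id, paired$unpaired$record_id)
  }
})

test_that("BEDPE round trip preserves count, types and 0-based coordinates", {
  set.seed(3)
  recs <- random_records(50)
  cs <- make_callset(recs)
  path <- tempfile(fileext = ".bedpe")
  write_bedpe(cs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 50)
  expect_equal(sort(back$name), sort(recs$record_id))
  m <- match(recs$record_id, back$name)
  expect_equal(back$start1[m], recs$start)
  expect_equal(back$start2[m] + 1L, recs$end)
  expect_equal(back$svtype[m], recs$svtype)
})

test_that("truth tables load with exact P/N accounting and strict cells", {
  path <- tempfile(fileext = ".tsv")
  set.seed(5)
  events <- sprintf("ev%02d", 1:10)
  m <- matrix(0L, 8, 10, dimnames = list(NULL, events))
  m[sample.int(80, 14)] <- 1L
  df <- data.frame(sample = sprintf("S%02d", 1:8), m, check.names = FALSE)
  readr::write_tsv(df, path)
  truth <- read_truth_table(path)
  expect_equal(nrow(truth), 80)
  expect_equal(truth_counts(truth)$P, 14)
  expect_equal(truth_counts(truth)$N, 66)

  # all-zero table
  df0 <- df
  df0[, events] <- 0L
  readr::write_tsv(df0, path)
  expect_equal(truth_counts(read_truth_table(path))$P, 0)

  # missing cell errors with sample and event named
  dfna <- df
  dfna$ev03[2] <- NA
  readr::write_tsv(dfna, path)
  expect_error(read_truth_table(path), "S02.*ev03")

  writeLines("sample", path)
  expect_error(read_truth_table(path), "empty")
})

test_that("arm maps form union spans of p/q bands", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "chr13\t0\t1000\tp11\tacen",
    "chr13\t1000\t5000\tq11\tgneg",
    "chr13\t5000\t9000\tq21\tgneg",
    "chr21\t0\t8000\tq11\tgneg"      # acrocentric: no p bands at all
  ), path)
  arms <- read_arm_map(path)
  q13 <- arms[arms$chrom == "13" & arms$arm == "q", ]
  expect_equal(c(q13$start, q13$end), c(1000, 9000))
  expect_false(any(arms$chrom == "21" & arms$arm == "p"))
  expect_true(any(arms$chrom == "21" & arms$arm == "q"))

  writeLines("chr9\t0\t1000\tp11\tgneg", path)
  expect_error(read_arm_map(path), "no q bands")
})

test_that("random band files produce min/max arm spans (oracle)", {
  set.seed(17)
  for (trial in 1:10) {
    n <- sample(5:30, 1)
    chrom <- sample(c("chr1", "chr2", "chr3"), n, replace = TRUE)
    start <- sample.int(1e6, n)
    width <- sample.int(1e5, n)
    arm <- sample(c("p", "q"), n, replace = TRUE)
    # ensure each chromosome has a q band and non-overlapping p/q ranges
    df <- data.frame(chrom = chrom, start = start, end = start + width,
                     band = paste0(arm, "11"), stain = "gneg")
    df$start[df$band == "q11"] <- df$start[df$band == "q11"] + 2e6
    df$end[df$band == "q11"] <- df$end[df$band == "q11"] + 2e6
    for (ch in unique(df$chrom)) {
      if (!any(df$chrom == ch & startsWith(df$band, "q"))) {
        df <- rbind(df, data.frame(chrom = ch, start = 3e6, end = 3.1e6,
                                   band = "q11", stain = "gneg"))
      }
    }
    path <- tempfile(fileext = ".tsv")
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    arms <- read_arm_map(path)
    for (i in seq_len(nrow(arms))) {
      sel <- sub("chr", "", df$chrom) == arms$chrom[i] &
        substr(df$band, 1, 1) == arms$arm[i]
      expect_equal(arms$start[i], min(df$start[sel]))
      expect_equal(arms$end[i], max(df$end[sel]))
    }
  }
})

test_that("the bundled synthetic hotspot catalog loads with the published category split", {
  cat <- read_hotspot_catalog(system.file("extdata", "hotspots_mm_synthetic.tsv",
                                          package = "svconcord"))
  expect_equal(nrow(cat), 68)
  expect_equal(sum(cat$category == "gain"), 49)
  expect_equal(sum(cat$category == "loss"), 19)
})

test_that("hotspot catalog validation rejects bad categories and duplicate ids", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\thotspot_id\tcategory",
               "1\t100\t200\tH1\tamplification"), path)
  expect_error(read_hotspot_catalog(path), "unknown hotspot category")
  writeLines(c("chrom\tstart\tend\thotspot_id\tcategory",
               "1\t100\t200\tH1\tgain",
               "2\t100\t200\tH1\tloss"), path)
  expect_error(read_hotspot_catalog(path), "duplicate")
  writeLines("chrom\tstart\tend\thotspot_id\tcategory", path)
  expect_equal(nrow(read_hotspot_catalog(path)), 0)
})
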