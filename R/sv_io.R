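#' @title SV callset input/output
#' @description Readers and writers for the formats the pipeline touches:
#'   Manta-dialect SV VCFs, BEDPE, cytoBand arm definitions, hotspot
#'   catalogs and FISH truth tables. All genomic coordinates are converted
#'   to 0-based half-open intervals at the I/O boundary; everything
#'   downstream assumes that single convention.
#' @name sv_io
NULL

SVTYPES <- c("DEL", "DUP", "INS", "INV", "BND")
BND_ORIENTATIONS <- c("t[p[", "t]p]", "]p]t", "[p[t")

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (the default policy) so that callsets,
#' cytoband files and catalogs from mixed sources key on the same names.
#'
#' @param chrom Character vector of chromosome names.
#' @param strip_chr Remove a leading "chr" prefix? Default `TRUE`.
#' @return Character vector of normalized names.
#' @export
normalize_chrom <- function(chrom, strip_chr = TRUE) {
  if (strip_chr) sub("^chr", "", chrom) else chrom
}

canonical_chrom_pair <- function(a, b) {
  purrr::map2_chr(a, b, function(x, y) paste(sort(c(x, y)), collapse = ":"))
}

empty_sv_records <- function() {
  tibble::tibble(
    record_id = character(), svtype = character(), chrom = character(),
    start = integer(), end = integer(), svlen = double(), qual = double(),
    filter = character(), mate_id = character(), mate_chrom = character(),
    mate_pos = integer(), orientation = character(), is_sub50 = logical()
  )
}

empty_translocations <- function() {
  tibble::tibble(
    id_a = character(), id_b = character(),
    chrom_a = character(), pos_a = integer(), orient_a = character(),
    chrom_b = character(), pos_b = integer(), orient_b = character(),
    chrom_pair = character(), inter = logical(),
    qual = double(), pass = logical()
  )
}

#' Construct an SV callset
#'
#' An `sv_callset` bundles the normalized SV records of one sample/platform
#' with, after [pair_breakends()], the assembled translocation events and
#' any breakends whose mate could not be resolved.
#'
#' @param records Tibble of SV records (see [read_sv_vcf()] for columns).
#' @param sample Sample identifier.
#' @param method Platform label, e.g. `"WES"` or `"linked-read"`.
#' @return An object of class `sv_callset`: a list with elements `sample`,
#'   `method`, `records`, `translocations`, `unpaired` and `paired`.
#' @export
sv_callset <- function(records, sample, method) {
  records <- dplyr::as_tibble(records)
  template <- empty_sv_records()
  missing_cols <- setdiff(names(template), names(records))
  for (nm in missing_cols) records[[nm]] <- rep(template[[nm]][NA_integer_], nrow(records))
  if (nrow(records) > 0) {
    bad_type <- !records$svtype %in% SVTYPES
    if (any(bad_type)) {
      stop("invalid svtype in records: ", paste(unique(records$svtype[bad_type]), collapse = ", "))
    }
    iv <- records$svtype != "BND"
    if (any(iv & (is.na(records$start) | is.na(records$end)))) {
      stop("non-BND records must carry an interval (start/end)")
    }
    if (any(iv & records$start >= records$end)) {
      stop("interval records must satisfy start < end")
    }
  }
  structure(
    list(
      sample = sample, method = method,
      records = records[, names(template)],
      translocations = empty_translocations(),
      unpaired = empty_sv_records(),
      paired = FALSE
    ),
    class = "sv_callset"
  )
}

#' @export
print.sv_callset <- function(x, ...) {
  cat("<sv_callset> sample=", x$sample, " method=", x$method, "\n", sep = "")
  if (nrow(x$records) > 0) {
    tab <- table(x$records$svtype)
    cat("  records: ", nrow(x$records), " (",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n", sep = "")
  } else {
    cat("  records: 0\n")
  }
  if (x$paired) {
    cat("  translocation events: ", nrow(x$translocations),
        "; unpaired breakends: ", nrow(x$unpaired), "\n", sep = "")
  } else {
    cat("  breakends not yet paired (run pair_breakends())\n")
  }
  invisible(x)
}

# Exact-key INFO field extraction: splits on ';' and matches the key
# exactly, so END never collides with CIEND and the like.
info_field <- function(info, key) {
  prefix <- paste0(key, "=")
  vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
    hit <- kv[startsWith(kv, prefix)]
    if (length(hit) > 0) return(sub("^[^=]+=", "", hit[[1]]))
    if (key %in% kv) return("TRUE")
    NA_character_
  }, character(1))
}

# Parse a VCF breakend ALT string into mate coordinates and one of the four
# bracket orientation classes. Returns a one-row list or NULL if malformed.
parse_bnd_alt <- function(alt) {
  pats <- c(
    "t[p[" = "^([A-Za-z.*]+)\\[([^:\\[\\]]+):([0-9]+)\\[$",
    "t]p]" = "^([A-Za-z.*]+)\\]([^:\\[\\]]+):([0-9]+)\\]$",
    "]p]t" = "^\\]([^:\\[\\]]+):([0-9]+)\\]([A-Za-z.*]+)$",
    "[p[t" = "^\\[([^:\\[\\]]+):([0-9]+)\\[([A-Za-z.*]+)$"
  )
  for (ori in names(pats)) {
    m <- regmatches(alt, regexec(pats[[ori]], alt, perl = TRUE))[[1]]
    if (length(m) == 4) {
      if (ori %in% c("t[p[", "t]p]")) {
        return(list(mate_chrom = m[3], mate_pos = as.integer(m[4]) - 1L, orientation = ori))
      }
      return(list(mate_chrom = m[2], mate_pos = as.integer(m[3]) - 1L, orientation = ori))
    }
  }
  NULL
}

#' Read a Manta-dialect SV VCF into an SV callset
#'
#' Parses the `SVTYPE`/`END`/`SVLEN`/`MATEID` INFO keys and BND ALT breakend
#' notation. VCF 1-based coordinates are converted to 0-based half-open
#' intervals: a record with `POS=100`, `END=200` becomes the interval
#' `[99, 200)`. Records failing the caller's FILTER are retained with their
#' filter strings — quality filtering is a downstream decision. Candidates
#' shorter than 50 bp are retained and flagged via `is_sub50`.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample Sample identifier to attach.
#' @param method Platform label to attach.
#' @param strip_chr Normalize chromosome names by stripping "chr"? Default
#'   `TRUE`.
#' @return An [sv_callset()] with breakends not yet paired.
#' @export
read_sv_vcf <- function(path, sample, method, strip_chr = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(sv_callset(empty_sv_records(), sample, method))
  }
  info <- unname(fix[, "INFO"])
  svtype <- info_field(info, "SVTYPE")
  if (any(is.na(svtype))) {
    stop("records missing SVTYPE at VCF data line(s): ",
         paste(which(is.na(svtype)), collapse = ", "))
  }
  bad <- !svtype %in% SVTYPES
  if (any(bad)) {
    stop("unsupported SVTYPE value(s): ", paste(unique(svtype[bad]), collapse = ", "))
  }
  chrom <- normalize_chrom(unname(fix[, "CHROM"]), strip_chr)
  pos <- as.integer(unname(fix[, "POS"]))
  id <- unname(fix[, "ID"])
  blank <- is.na(id) | id == "."
  id[blank] <- sprintf("rec%06d", which(blank))
  end_info <- suppressWarnings(as.numeric(info_field(info, "END")))
  svlen <- suppressWarnings(as.numeric(sub(",.*", "", info_field(info, "SVLEN"))))
  mateid <- info_field(info, "MATEID")
  qual <- suppressWarnings(as.numeric(unname(fix[, "QUAL"])))
  filt <- unname(fix[, "FILTER"])
  filt[is.na(filt)] <- "."

  start0 <- pos - 1L
  end0 <- rep(NA_integer_, length(pos))
  is_bnd <- svtype == "BND"
  ins <- svtype == "INS"
  iv <- !is_bnd
  end0[iv] <- as.integer(ifelse(!is.na(end_info[iv]), end_info[iv],
    ifelse(ins[iv], pos[iv],
      ifelse(!is.na(svlen[iv]), pos[iv] - 1 + abs(svlen[iv]), NA))))
  if (any(iv & is.na(end0))) {
    stop("interval records lacking both END and SVLEN at line(s): ",
         paste(which(iv & is.na(end0)), collapse = ", "))
  }

  mate_chrom <- rep(NA_character_, length(pos))
  mate_pos <- rep(NA_integer_, length(pos))
  orientation <- rep(NA_character_, length(pos))
  if (any(is_bnd)) {
    alt <- unname(fix[, "ALT"])
    for (i in which(is_bnd)) {
      bk <- parse_bnd_alt(alt[i])
      if (is.null(bk)) stop("malformed BND ALT for record id '", id[i], "': ", alt[i])
      mate_chrom[i] <- normalize_chrom(bk$mate_chrom, strip_chr)
      mate_pos[i] <- bk$mate_pos
      orientation[i] <- bk$orientation
    }
    start0[is_bnd] <- pos[is_bnd] - 1L
    end0[is_bnd] <- NA_integer_
  }

  records <- tibble::tibble(
    record_id = id, svtype = svtype, chrom = chrom,
    start = start0, end = end0, svlen = svlen, qual = qual,
    filter = filt, mate_id = mateid, mate_chrom = mate_chrom,
    mate_pos = mate_pos, orientation = orientation,
    is_sub50 = !is.na(svlen) & abs(svlen) < 50
  )
  sv_callset(records, sample, method)
}

#' Assemble translocation events from paired breakends
#'
#' Collapses mutually referencing BND record pairs (linked by `MATEID`) into
#' one translocation event each. Breakends whose mate is absent or does not
#' reference back are moved to `unpaired`, never dropped silently. The
#' operation is idempotent and invariant to record order.
#'
#' @param callset An [sv_callset()].
#' @return The callset with `translocations`, `unpaired` filled in and
#'   `paired = TRUE`.
#' @export
pair_breakends <- function(callset) {
  stopifnot(inherits(callset, "sv_callset"))
  recs <- callset$records
  bnd <- recs[recs$svtype == "BND", , drop = FALSE]
  callset$translocations <- empty_translocations()
  callset$unpaired <- empty_sv_records()
  callset$paired <- TRUE
  if (nrow(bnd) == 0) return(callset)

  idx <- match(bnd$mate_id, bnd$record_id)             # position of claimed mate
  mate_of_mate <- bnd$mate_id[idx]
  mutual <- !is.na(idx) & !is.na(mate_of_mate) & mate_of_mate == bnd$record_id &
    bnd$record_id != bnd$mate_id
  # a record id appearing more than once cannot be paired unambiguously
  dup <- bnd$record_id %in% bnd$record_id[duplicated(bnd$record_id)]
  dup_mate <- ifelse(is.na(idx), FALSE, dup[idx])
  mutual <- mutual & !dup & !dup_mate

  first_of_pair <- mutual & seq_len(nrow(bnd)) < idx
  a <- bnd[which(first_of_pair), , drop = FALSE]
  b <- bnd[idx[which(first_of_pair)], , drop = FALSE]
  if (nrow(a) > 0) {
    callset$translocations <- tibble::tibble(
      id_a = a$record_id, id_b = b$record_id,
      chrom_a = a$chrom, pos_a = a$start, orient_a = a$orientation,
      chrom_b = b$chrom, pos_b = b$start, orient_b = b$orientation,
      chrom_pair = canonical_chrom_pair(a$chrom, b$chrom),
      inter = a$chrom != b$chrom,
      qual = pmin(a$qual, b$qual),
      pass = a$filter == "PASS" & b$filter == "PASS"
    )
  }
  callset$unpaired <- bnd[!mutual, , drop = FALSE]
  callset
}

#' Write a callset to BEDPE
#'
#' One line per record, 0-based half-open, tab-delimited. Interval records
#' report their two breakpoints (start and end); BND records report the
#' local and mate breakends.
#'
#' @param callset An [sv_callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(callset, path) {
  r <- callset$records
  is_bnd <- r$svtype == "BND"
  out <- tibble::tibble(
    chrom1 = r$chrom,
    start1 = r$start,
    end1 = r$start + 1L,
    chrom2 = ifelse(is_bnd, r$mate_chrom, r$chrom),
    start2 = ifelse(is_bnd, r$mate_pos, r$end - 1L),
    end2 = ifelse(is_bnd, r$mate_pos + 1L, r$end),
    name = r$record_id,
    score = ifelse(is.na(r$qual), ".", as.character(r$qual)),
    svtype = r$svtype,
    svlen = ifelse(is.na(r$svlen), ".", as.character(r$svlen)),
    filter = r$filter
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a FISH truth table
#'
#' Expects a delimited table with one row per sample, a `sample` column (or
#' first column treated as such) and one 0/1 column per panel event.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter, default tab.
#' @return Long tibble with columns `sample`, `event_id`, `label` (0/1).
#' @export
read_truth_table <- function(path, delim = "\t") {
  wide <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if (nrow(wide) == 0 || ncol(wide) < 2) stop("empty or column-less truth table: ", path)
  names(wide)[1] <- "sample"
  long <- tidyr::pivot_longer(wide, -"sample", names_to = "event_id", values_to = "label")
  bad <- is.na(long$label) | !long$label %in% c(0, 1)
  if (any(bad)) {
    culprit <- long[which(bad)[1], ]
    stop("missing or non-binary truth cell for sample '", culprit$sample,
         "', event '", culprit$event_id, "'")
  }
  long$label <- as.integer(long$label)
  long
}

#' Positive/negative counts of a truth table
#'
#' @param truth Long truth tibble from [read_truth_table()].
#' @return One-row tibble with `P` (positives), `N` (negatives).
#' @export
truth_counts <- function(truth) {
  tibble::tibble(P = sum(truth$label == 1L), N = sum(truth$label == 0L))
}

#' Read chromosome arm definitions from a cytoBand file
#'
#' UCSC cytoBand format (chrom, start, end, band, stain; no header). The p
#' and q arm of each chromosome are formed as the union span of its p* and
#' q* bands. Acrocentric chromosomes may lack p bands; a chromosome with no
#' q bands is an error.
#'
#' @param path Path to a cytoBand TSV.
#' @param strip_chr Normalize chromosome names? Default `TRUE`.
#' @return Tibble with columns `chrom`, `arm` ("p"/"q"), `start`, `end`
#'   (0-based half-open).
#' @export
read_arm_map <- function(path, strip_chr = TRUE) {
  bands <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "band", "stain"),
    col_types = "cnncc"
  )
  bands$arm <- substr(bands$band, 1, 1)
  bands <- bands[bands$arm %in% c("p", "q"), , drop = FALSE]
  if (nrow(bands) == 0) stop("no p/q bands found in ", path)
  bands$chrom <- normalize_chrom(bands$chrom, strip_chr)
  arms <- bands |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  no_q <- setdiff(unique(arms$chrom), arms$chrom[arms$arm == "q"])
  if (length(no_q) > 0) {
    stop("chromosome(s) with no q bands: ", paste(no_q, collapse = ", "))
  }
  wide <- tidyr::pivot_wider(arms, names_from = "arm", values_from = c("start", "end"))
  if ("start_p" %in% names(wide)) {
    bad <- !is.na(wide$start_p) & wide$end_p > wide$start_q
    if (any(bad)) {
      stop("overlapping p/q arms on chromosome(s): ",
           paste(wide$chrom[bad], collapse = ", "))
    }
  }
  dplyr::arrange(arms, .data$chrom, .data$arm)
}

#' Bundled arm-level cytoband map (GRCh38, coarse)
#'
#' A two-band-per-chromosome cytoBand file with approximate GRCh38
#' centromere boundaries — arm-level resolution, which is all the panel
#' semantics require. Supply a full cytoBand file via [read_arm_map()] for
#' band-accurate arms.
#'
#' @return Arm tibble as from [read_arm_map()].
#' @export
default_arm_map <- function() {
  read_arm_map(system.file("extdata", "cytoband_arms_grch38.tsv",
                           package = "svconcord", mustWork = TRUE))
}

#' Read an SV hotspot catalog
#'
#' Delimited table with header columns `chrom`, `start`, `end`,
#' `hotspot_id`, `category`; categories are `gain`, `loss` or `fragile`.
#'
#' @param path Path to the catalog TSV.
#' @param strip_chr Normalize chromosome names? Default `TRUE`.
#' @return Tibble of catalog entries.
#' @export
read_hotspot_catalog <- function(path, strip_chr = TRUE) {
  cat <- readr::read_tsv(path, col_types = "cnncc")
  needed <- c("chrom", "start", "end", "hotspot_id", "category")
  if (!all(needed %in% names(cat))) {
    stop("hotspot catalog must have columns: ", paste(needed, collapse = ", "))
  }
  bad <- !cat$category %in% c("gain", "loss", "fragile")
  if (any(bad)) {
    stop("unknown hotspot category value(s): ",
         paste(unique(cat$category[bad]), collapse = ", "))
  }
  if (anyDuplicated(cat$hotspot_id)) {
    stop("duplicate hotspot id(s): ",
         paste(unique(cat$hotspot_id[duplicated(cat$hotspot_id)]), collapse = ", "))
  }
  if (nrow(cat) > 0 && any(cat$start >= cat$end)) stop("invalid hotspot interval (start >= end)")
  cat$chrom <- normalize_chrom(cat$chrom, strip_chr)
  cat
}
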