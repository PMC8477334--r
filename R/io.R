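# Reading and writing clonotype tables, sample metadata and cohort assembly.
#
# The canonical interchange format is the AIRR Rearrangement TSV; a
# TRUST-style TSV dialect is mapped onto the same record layout at read
# time. A clonotype record is one observed CDR3 amino-acid sequence in one
# sample with its supporting read count and chain.

.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWY"
.CHAINS <- c("TRA", "TRB", "TRG", "TRD")

.airr_cols <- c(sample_id = "repertoire_id", cdr3_aa = "junction_aa",
                cdr3_nt = "junction", chain = "locus", v_call = "v_call",
                j_call = "j_call", read_count = "duplicate_count")
.trust_cols <- c(sample_id = "sample", read_count = "count",
                 cdr3_aa = "CDR3aa", cdr3_nt = "CDR3nt",
                 v_call = "Vgene", j_call = "Jgene", chain = "chain")

.normalize_chain <- function(x) {
  x <- toupper(trimws(ifelse(is.na(x), "", x)))
  ifelse(x %in% .CHAINS, x, "unknown")
}

.valid_cdr3 <- function(x) {
  grepl(sprintf("^[%s]+$", .AA_ALPHABET), x)
}

#' Read a clonotype table
#'
#' Parses an AIRR Rearrangement TSV or a TRUST-style TSV into a tibble of
#' clonotype records. Read counts are parsed as integers (TRUST fractional
#' read estimates are rounded half-up); rows with zero or negative counts
#' are dropped with a message, as are CDR3 amino-acid strings containing
#' stop codons (`*`), ambiguous residues (`X`) or other characters outside
#' the 20-letter alphabet — non-productive or ambiguous assemblies cannot
#' be matched across samples.
#'
#' @param path Path to a tab-separated clonotype table.
#' @param dialect `"airr"` (columns `repertoire_id`, `junction_aa`,
#'   `junction`, `locus`, `v_call`, `j_call`, `duplicate_count`) or
#'   `"trust"` (columns `sample`, `count`, `CDR3aa`, `CDR3nt`, `Vgene`,
#'   `Jgene`, `chain`; `#`-comment lines are skipped).
#' @return A tibble with columns `sample_id`, `cdr3_aa`, `cdr3_nt`,
#'   `chain`, `v_call`, `j_call`, `read_count`, one row per input row
#'   (duplicates are preserved; aggregation happens in [build_cohort()]).
#' @seealso [filter_short_cdr3()], [build_cohort()], [write_airr()]
#' @export
read_clonotype_table <- function(path, dialect = c("airr", "trust")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("clonotype table not found: ", path)
  comment <- if (dialect == "trust") "#" else ""
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = comment,
                           check.names = FALSE, na.strings = NULL)
  map <- if (dialect == "airr") .airr_cols else .trust_cols
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required ", dialect, " column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rec <- tibble::tibble(
    sample_id = raw[[map[["sample_id"]]]],
    cdr3_aa   = toupper(trimws(raw[[map[["cdr3_aa"]]]])),
    cdr3_nt   = raw[[map[["cdr3_nt"]]]],
    chain     = .normalize_chain(raw[[map[["chain"]]]]),
    v_call    = raw[[map[["v_call"]]]],
    j_call    = raw[[map[["j_call"]]]]
  )
  count_raw <- trimws(raw[[map[["read_count"]]]])
  count_num <- suppressWarnings(as.numeric(count_raw))
  bad <- which(!is.finite(count_num))
  if (length(bad) > 0) {
    stop("unparseable read count ", dQuote(count_raw[bad[1]]),
         " at data line ", bad[1], " of ", path)
  }
  # round half-up so TRUST fractional estimates become integer counts
  rec$read_count <- as.integer(floor(count_num + 0.5))

  nonpos <- rec$read_count < 1L
  if (any(nonpos)) {
    message(sum(nonpos), " row(s) with zero/negative read count dropped")
    rec <- rec[!nonpos, , drop = FALSE]
  }
  invalid <- !.valid_cdr3(rec$cdr3_aa)
  if (any(invalid)) {
    message(sum(invalid),
            " CDR3 sequence(s) with non-standard residues dropped")
    rec <- rec[!invalid, , drop = FALSE]
  }
  rec
}

#' Drop short CDR3 sequences
#'
#' CDR3 amino-acid sequences shorter than `min_aa` residues are excluded;
#' such fragments are likely incomplete assemblies. Order is preserved and
#' the operation is idempotent.
#'
#' @param records Clonotype record tibble from [read_clonotype_table()].
#' @param min_aa Minimum CDR3 length in amino acids (default 6; sequences
#'   of fewer than six residues are excluded).
#' @return The records with `nchar(cdr3_aa) >= min_aa`.
#' @export
filter_short_cdr3 <- function(records, min_aa = 6L) {
  stopifnot(min_aa >= 1)
  records[nchar(records$cdr3_aa) >= min_aa, , drop = FALSE]
}

#' Read sample metadata
#'
#' @param path Tab-separated file with columns `sample_id`, `patient_id`,
#'   `location`, `timepoint`, `sample_type`, `subtype`, `outcome`.
#' @return A tibble with `timepoint` as integer; `subtype`/`outcome` may be
#'   `NA`/`"unknown"`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "patient_id", "location", "timepoint",
                "sample_type", "subtype", "outcome")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required metadata column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- tibble::as_tibble(raw[required])
  meta$timepoint <- as.integer(meta$timepoint)
  bad_type <- !meta$sample_type %in% c("biopsy", "brush")
  if (any(bad_type)) {
    stop("sample_type must be 'biopsy' or 'brush'; offending sample(s): ",
         paste(utils::head(meta$sample_id[bad_type], 5), collapse = ", "))
  }
  meta$outcome[meta$outcome == "" | is.na(meta$outcome)] <- "unknown"
  .check_metadata_unique(meta)
  meta
}

.check_metadata_unique <- function(meta) {
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  }
  bio <- meta[meta$sample_type == "biopsy", , drop = FALSE]
  key <- paste(bio$patient_id, bio$location, bio$timepoint)
  if (anyDuplicated(key)) {
    stop("more than one biopsy for the same (patient, location, timepoint): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  invisible(meta)
}

#' Clonotype identity keys
#'
#' The clonotype identity used throughout the package is the pair
#' (chain, CDR3 amino-acid sequence); V/J calls and the nucleotide sequence
#' are ignored when matching across samples. Setting `pool_chains = TRUE`
#' collapses the key to the CDR3 sequence alone.
#'
#' @param records Clonotype records.
#' @param pool_chains Match CDR3 sequences across chains.
#' @return Character vector of keys, one per record.
#' @export
clonotype_key <- function(records, pool_chains = FALSE) {
  if (pool_chains) records$cdr3_aa else paste0(records$chain, ":", records$cdr3_aa)
}

#' Assemble a cohort repertoire
#'
#' Aggregates duplicate (sample, clonotype) rows by summing read counts and
#' computes the cohort clonotype universe and per-sample totals. Every
#' record's `sample_id` must be present in the metadata.
#'
#' @param records Clonotype record tibble.
#' @param metadata Sample metadata tibble (see [read_sample_metadata()]).
#' @param pool_chains Collapse clonotype identity across chains (default
#'   `FALSE`: the key is chain + CDR3, avoiding cross-locus collisions).
#' @return A `tcr_cohort` object: a list with `records` (aggregated, with a
#'   `key` column), `samples` (metadata), `universe` (distinct keys),
#'   `totals` (per-sample `total_reads`, `unique_clonotypes`) and
#'   `pool_chains`.
#' @export
build_cohort <- function(records, metadata, pool_chains = FALSE) {
  .check_metadata_unique(metadata)
  orphan <- setdiff(unique(records$sample_id), metadata$sample_id)
  if (length(orphan) > 0) {
    stop("records refer to sample_id(s) absent from metadata: ",
         paste(orphan, collapse = ", "))
  }
  stopifnot(all(records$read_count >= 1))
  if (nrow(records) == 0) {
    rec <- tibble::as_tibble(records)
    rec$key <- character(0)
    return(structure(
      list(records = rec, samples = tibble::as_tibble(metadata),
           universe = character(0),
           totals = tibble::tibble(sample_id = metadata$sample_id,
                                   total_reads = 0L,
                                   unique_clonotypes = 0L),
           pool_chains = pool_chains),
      class = "tcr_cohort"))
  }
  key <- clonotype_key(records, pool_chains)
  agg_id <- paste0(records$sample_id, "\r", key)
  first <- !duplicated(agg_id)
  counts <- tapply(records$read_count, agg_id, sum)
  rec <- records[first, , drop = FALSE]
  rec$key <- key[first]
  rec$read_count <- as.integer(counts[agg_id[first]])
  rec <- rec[order(rec$sample_id, rec$key), , drop = FALSE]
  rec <- tibble::as_tibble(rec)

  sid <- factor(rec$sample_id, levels = metadata$sample_id)
  totals <- tibble::tibble(
    sample_id = metadata$sample_id,
    total_reads = as.integer(tapply(rec$read_count, sid, sum, default = 0L)),
    unique_clonotypes = as.integer(tabulate(sid, nbins = nrow(metadata)))
  )

  structure(
    list(records = rec, samples = tibble::as_tibble(metadata),
         universe = sort(unique(rec$key)), totals = totals,
         pool_chains = pool_chains),
    class = "tcr_cohort"
  )
}

#' @export
print.tcr_cohort <- function(x, ...) {
  n_bio <- sum(x$samples$sample_type == "biopsy")
  n_bru <- sum(x$samples$sample_type == "brush")
  cat("TCR cohort repertoire\n")
  cat("  samples:    ", nrow(x$samples), " (", n_bio, " biopsies, ",
      n_bru, " brushes), ", length(unique(x$samples$patient_id)),
      " patients\n", sep = "")
  cat("  clonotypes: ", length(x$universe), " distinct (key: ",
      if (x$pool_chains) "CDR3 aa, chains pooled" else "chain + CDR3 aa",
      ")\n", sep = "")
  cat("  TCR reads:  ", sum(x$totals$total_reads), "\n", sep = "")
  invisible(x)
}

#' Subset a cohort to selected samples
#'
#' Universe and totals are recomputed for the retained samples.
#'
#' @param cohort A `tcr_cohort`.
#' @param sample_ids Samples to keep.
#' @return A `tcr_cohort` restricted to `sample_ids`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  meta <- cohort$samples[cohort$samples$sample_id %in% sample_ids, , drop = FALSE]
  rec <- cohort$records[cohort$records$sample_id %in% sample_ids, , drop = FALSE]
  build_cohort(rec[setdiff(names(rec), "key")], meta,
               pool_chains = cohort$pool_chains)
}

#' Write a cohort's records as an AIRR Rearrangement TSV
#'
#' The written file round-trips through [read_clonotype_table()] with
#' `dialect = "airr"`. Records with chain `"unknown"` are emitted with an
#' empty `locus` field.
#'
#' @param cohort A `tcr_cohort` (or a bare record tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(cohort, path) {
  rec <- if (inherits(cohort, "tcr_cohort")) cohort$records else cohort
  out <- data.frame(
    repertoire_id = rec$sample_id,
    locus = ifelse(rec$chain == "unknown", "", rec$chain),
    junction_aa = rec$cdr3_aa,
    junction = ifelse(is.na(rec$cdr3_nt), "", rec$cdr3_nt),
    v_call = ifelse(is.na(rec$v_call), "", rec$v_call),
    j_call = ifelse(is.na(rec$j_call), "", rec$j_call),
    duplicate_count = rec$read_count,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#'
#' @param metadata Sample metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
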