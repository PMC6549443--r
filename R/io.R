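#' Read a FASTA file into a DNAStringSet
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that enforces the
#' invariants the rest of the pipeline relies on: sequence ids unique within
#' the set, no empty sequences, sequences uppercased. The id is the first
#' whitespace-delimited token of the header, as produced by assemblers and
#' reference FASTA files alike.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A [Biostrings::DNAStringSet] named by sequence id.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(names(seqs) == "")) {
    stop("FASTA record with empty header in '", path, "'")
  }
  empty <- Biostrings::width(seqs) == 0L
  if (any(empty)) {
    stop("FASTA record(s) with empty sequence in '", path, "': ",
         paste(names(seqs)[empty], collapse = ", "))
  }
  dup <- duplicated(names(seqs))
  if (any(dup)) {
    stop("duplicate sequence id(s) in '", path, "': ",
         paste(unique(names(seqs)[dup]), collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector or DNAStringSet.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Sequence lengths as a named integer vector
#'
#' @param seqs DNAStringSet or named character vector.
#' @return Named integer vector of lengths in nucleotides.
#' @export
seq_lengths <- function(seqs) {
  if (is.character(seqs)) {
    stats::setNames(nchar(seqs), names(seqs))
  } else {
    stats::setNames(Biostrings::width(seqs), names(seqs))
  }
}

#' Drop sequences at or below a length cutoff
#'
#' Assemblies are conventionally restricted to contigs longer than 500 nt
#' before evaluation, to reduce the influence of fragmented contigs. The
#' cutoff is strict by default (length > `min_len` is kept); set
#' `inclusive = TRUE` to keep sequences of exactly `min_len`.
#'
#' @param seqs DNAStringSet.
#' @param min_len Length cutoff in nt (default 500).
#' @param inclusive Keep sequences of exactly `min_len`? Default `FALSE`.
#' @return The filtered DNAStringSet.
#' @export
filter_min_length <- function(seqs, min_len = 500L, inclusive = FALSE) {
  stopifnot(min_len >= 0)
  w <- Biostrings::width(seqs)
  keep <- if (inclusive) w >= min_len else w > min_len
  seqs[keep]
}

.blast_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Parses the default 12-column tab-separated BLAST output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore), one HSP per row, no header. Subject coordinates on the
#' minus strand (sstart > send) are normalized to `(min, max)` and flagged
#' in the `minus_strand` column. `n_identical` is derived as
#' `round(pident/100 * length)`; the 12-column dialect does not carry an
#' identical-bases column.
#'
#' @param path Path to a BLAST tabular file.
#' @return A data.frame of HSP records with columns `qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore, minus_strand, n_identical`. Coordinates are 1-based
#'   inclusive.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hsp_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 12L)
  if (length(bad) > 0L) {
    stop("BLAST tabular row ", bad[1L], " in '", path, "' has ", nf[bad[1L]],
         " columns; expected 12")
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  hsp <- data.frame(
    qseqid = m[, 1L], sseqid = m[, 2L],
    pident = as.numeric(m[, 3L]), length = as.integer(m[, 4L]),
    mismatch = as.integer(m[, 5L]), gapopen = as.integer(m[, 6L]),
    qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
    sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
    evalue = as.numeric(m[, 11L]), bitscore = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  normalize_hsp_coords(hsp)
}

#' Normalize HSP coordinates to forward orientation
#'
#' Ensures `qstart <= qend` and `sstart <= send`, recording reverse subject
#' orientation in `minus_strand`, and derives `n_identical`. Idempotent.
#'
#' @param hsp HSP data.frame as from [read_blast_tabular()].
#' @return The normalized data.frame.
#' @export
normalize_hsp_coords <- function(hsp) {
  if (is.null(hsp$minus_strand)) hsp$minus_strand <- FALSE
  rev_s <- hsp$sstart > hsp$send
  if (any(rev_s)) {
    tmp <- hsp$sstart[rev_s]
    hsp$sstart[rev_s] <- hsp$send[rev_s]
    hsp$send[rev_s] <- tmp
    hsp$minus_strand[rev_s] <- TRUE
  }
  rev_q <- hsp$qstart > hsp$qend
  if (any(rev_q)) {
    tmp <- hsp$qstart[rev_q]
    hsp$qstart[rev_q] <- hsp$qend[rev_q]
    hsp$qend[rev_q] <- tmp
  }
  bad <- hsp$pident < 0 | hsp$pident > 100 | hsp$evalue < 0
  if (any(bad)) {
    stop("HSP row(s) with pident outside [0,100] or negative evalue: ",
         paste(which(bad), collapse = ", "))
  }
  hsp$n_identical <- as.integer(round(hsp$pident / 100 * hsp$length))
  hsp
}

empty_hsp_table <- function() {
  data.frame(
    qseqid = character(0), sseqid = character(0),
    pident = numeric(0), length = integer(0),
    mismatch = integer(0), gapopen = integer(0),
    qstart = integer(0), qend = integer(0),
    sstart = integer(0), send = integer(0),
    evalue = numeric(0), bitscore = numeric(0),
    minus_strand = logical(0), n_identical = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Write HSP records in BLAST tabular format
#'
#' Inverse of [read_blast_tabular()]: emits the 12 standard columns,
#' restoring reversed subject coordinates for minus-strand rows so that a
#' read/write round trip reproduces the records.
#'
#' @param hsp HSP data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tabular <- function(hsp, path) {
  out <- hsp
  if (!is.null(out$minus_strand)) {
    rev_s <- out$minus_strand
    tmp <- out$sstart[rev_s]
    out$sstart[rev_s] <- out$send[rev_s]
    out$send[rev_s] <- tmp
  }
  out <- out[, .blast_cols]
  out$pident <- formatC(out$pident, format = "f", digits = 2)
  out$evalue <- formatC(out$evalue, format = "g", digits = 3)
  out$bitscore <- formatC(out$bitscore, format = "f", digits = 1)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a quantifier abundance table
#'
#' Normalizes the per-sequence abundance outputs of the common quantifiers
#' into one record layout. Supported dialects:
#' \describe{
#'   \item{kallisto}{`abundance.tsv`: target_id, length, eff_length,
#'     est_counts, tpm}
#'   \item{salmon}{`quant.sf`: Name, Length, EffectiveLength, TPM, NumReads}
#'   \item{rsem}{`.isoforms.results`: transcript_id, length,
#'     effective_length, expected_count, TPM (among other columns)}
#'   \item{groundtruth-tsv}{seq_id, read_count, length; effective length and
#'     TPM are computed downstream (see [effective_length()] and
#'     [ground_truth_tpm()]) and left `NA` here}
#' }
#'
#' @param path Path to the abundance table (header line present).
#' @param dialect One of `"kallisto"`, `"salmon"`, `"rsem"`,
#'   `"groundtruth-tsv"`.
#' @return A data.frame with columns `seq_id, read_count, length,
#'   effective_length, tpm`.
#' @export
read_abundance <- function(path,
                           dialect = c("kallisto", "salmon", "rsem",
                                       "groundtruth-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("abundance table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- switch(dialect,
    "kallisto" = c(id = "target_id", len = "length", eff = "eff_length",
                   count = "est_counts", tpm = "tpm"),
    "salmon" = c(id = "Name", len = "Length", eff = "EffectiveLength",
                 count = "NumReads", tpm = "TPM"),
    "rsem" = c(id = "transcript_id", len = "length",
               eff = "effective_length", count = "expected_count",
               tpm = "TPM"),
    "groundtruth-tsv" = c(id = "seq_id", count = "read_count", len = "length")
  )
  missing_cols <- setdiff(unname(need), colnames(tab))
  if (length(missing_cols) > 0L) {
    stop("abundance table '", path, "' (dialect ", dialect,
         ") is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(tab)
  data.frame(
    seq_id = as.character(tab[[need[["id"]]]]),
    read_count = as.numeric(tab[[need[["count"]]]]),
    length = as.integer(tab[[need[["len"]]]]),
    effective_length = if ("eff" %in% names(need))
      as.numeric(tab[[need[["eff"]]]]) else rep(NA_real_, n),
    tpm = if ("tpm" %in% names(need))
      as.numeric(tab[[need[["tpm"]]]]) else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
}

#' Write an abundance table in a quantifier dialect
#'
#' @param expr Expression data.frame as from [read_abundance()].
#' @param path Output path.
#' @param dialect Output dialect; same choices as [read_abundance()].
#' @return `path`, invisibly.
#' @export
write_abundance <- function(expr, path,
                            dialect = c("kallisto", "salmon", "rsem",
                                        "groundtruth-tsv")) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    "kallisto" = data.frame(
      target_id = expr$seq_id, length = expr$length,
      eff_length = expr$effective_length, est_counts = expr$read_count,
      tpm = expr$tpm, stringsAsFactors = FALSE),
    "salmon" = data.frame(
      Name = expr$seq_id, Length = expr$length,
      EffectiveLength = expr$effective_length, TPM = expr$tpm,
      NumReads = expr$read_count, stringsAsFactors = FALSE),
    "rsem" = data.frame(
      transcript_id = expr$seq_id, gene_id = expr$seq_id,
      length = expr$length, effective_length = expr$effective_length,
      expected_count = expr$read_count, TPM = expr$tpm,
      FPKM = 0, IsoPct = 100, stringsAsFactors = FALSE),
    "groundtruth-tsv" = data.frame(
      seq_id = expr$seq_id, read_count = expr$read_count,
      length = expr$length, stringsAsFactors = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
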