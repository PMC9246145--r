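#' Read coding sequences from a FASTA file
#'
#' Gene identifiers are taken as the first whitespace-delimited token of each
#' FASTA header; sequences are upper-cased. No filtering is performed here,
#' see [filter_genes()].
#'
#' @param path Path to a (possibly gzipped) FASTA file of coding sequences,
#'   one record per protein-coding gene.
#' @return A data.frame with columns `gene_id` and `sequence`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  data.frame(
    gene_id = ids,
    sequence = toupper(as.character(seqs)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write gene records to FASTA
#'
#' @param records Data.frame with `gene_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Filter coding sequences prior to codon-usage analysis
#'
#' A gene is retained iff its id is not excluded, the sequence contains only
#' A/C/G/T, its length is a multiple of three, it begins with the canonical
#' ATG start, and it contains no stop codon except (optionally) the final
#' codon. Rejections are reported, never raised.
#'
#' @param records Data.frame as returned by [read_cds_fasta()] (extra columns
#'   are carried through).
#' @param exclusion_ids Character vector of gene ids to drop a priori (e.g.
#'   mitochondrial genes).
#' @param genetic_code A [genetic_code()] object (source of stop codons).
#' @return A list with `retained` (subset of `records`) and `rejected`
#'   (data.frame `gene_id`, `reason` with reasons among `excluded`,
#'   `ambiguous_bases`, `length_not_multiple_of_3`, `non_canonical_start`,
#'   `internal_stop`).
#' @export
filter_genes <- function(records, exclusion_ids = character(),
                         genetic_code = codonregimes::genetic_code()) {
  stopifnot(is.data.frame(records), all(c("gene_id", "sequence") %in% names(records)))
  reason <- rep(NA_character_, nrow(records))
  seqs <- toupper(records$sequence)

  reason[records$gene_id %in% exclusion_ids] <- "excluded"
  ok <- is.na(reason)
  bad_alpha <- grepl("[^ACGT]", seqs)
  reason[ok & bad_alpha] <- "ambiguous_bases"
  ok <- is.na(reason)
  bad_len <- nchar(seqs) %% 3L != 0L | nchar(seqs) < 6L
  reason[ok & bad_len] <- "length_not_multiple_of_3"
  ok <- is.na(reason)
  bad_start <- substr(seqs, 1L, 3L) != "ATG"
  reason[ok & bad_start] <- "non_canonical_start"
  ok <- which(is.na(reason))
  for (i in ok) {
    cods <- codon_split(seqs[i])
    internal <- cods[-length(cods)]
    if (any(internal %in% genetic_code$stop_codons)) reason[i] <- "internal_stop"
  }

  keep <- is.na(reason)
  list(
    retained = records[keep, , drop = FALSE],
    rejected = data.frame(
      gene_id = records$gene_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}

codon_split <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Count sense codons of a single coding sequence
#'
#' The initiator ATG is excluded by default (initiation is constrained
#' independently of synonymous codon choice) and a terminal stop codon, when
#' present, is always excluded (stop codons are not sense codons). The count
#' vector therefore sums to `len/3 - 1 - [terminal stop present]` by default.
#'
#' @param sequence A coding sequence that passed [filter_genes()].
#' @param genetic_code A [genetic_code()] object.
#' @param count_start_codon Include the initiator codon in the counts.
#' @return Named integer vector over the 61 sense codons (alphabetical).
#' @export
count_codons <- function(sequence, genetic_code = codonregimes::genetic_code(),
                         count_start_codon = FALSE) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("sequence contains non-ACGT characters")
  if (nchar(sequence) %% 3L != 0L) stop("sequence length is not a multiple of 3")
  cods <- codon_split(sequence)
  if (length(cods) >= 1L && cods[length(cods)] %in% genetic_code$stop_codons) {
    cods <- cods[-length(cods)]
  }
  if (any(cods %in% genetic_code$stop_codons)) stop("internal stop codon in sequence")
  if (!count_start_codon) cods <- cods[-1L]
  counts <- table(factor(cods, levels = genetic_code$codons))
  stats::setNames(as.integer(counts), genetic_code$codons)
}

#' GC3 content from a codon count vector
#'
#' Fraction of counted codons whose third base is G or C, computed over all
#' sense codons (1- and 2-fold families included).
#'
#' @param counts Named count vector (names are codons) or a genes-by-codons
#'   count matrix, in which case a per-gene vector is returned.
#' @return Fraction(s) in \[0, 1\].
#' @export
gc3_percent <- function(counts) {
  if (is.matrix(counts)) {
    tot <- rowSums(counts)
    if (any(tot <= 0)) stop("all rows must have positive codon counts")
    gc_cols <- substr(colnames(counts), 3L, 3L) %in% c("G", "C")
    return(rowSums(counts[, gc_cols, drop = FALSE]) / tot)
  }
  tot <- sum(counts)
  if (tot <= 0) stop("count vector sums to zero")
  gc <- substr(names(counts), 3L, 3L) %in% c("G", "C")
  sum(counts[gc]) / tot
}

#' Assemble a codon count table
#'
#' Translates filtered gene records into a genes-by-61-codons count matrix
#' with per-gene GC3 and optional chromosome coordinates. Gene order follows
#' the input; coordinates are ordinal gene indices along each chromosome (the
#' window statistics operate on gene ranks, not base pairs).
#'
#' @param records Data.frame of retained genes (`gene_id`, `sequence`).
#' @param genetic_code A [genetic_code()] object.
#' @param metadata Optional data.frame `gene_id`, `chromosome`, `position`.
#'   Ids absent from `metadata` get `NA` coordinates with a warning.
#' @param count_start_codon Passed to the codon counter.
#' @return An object of class `codon_count_table`: list with `gene_ids`,
#'   `counts` (integer matrix, rownames = gene ids, colnames = codons), `gc3`
#'   (named numeric), `coords` (data.frame or `NULL`) and `genetic_code`.
#' @export
build_count_table <- function(records, genetic_code = codonregimes::genetic_code(),
                              metadata = NULL, count_start_codon = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  if (anyDuplicated(records$gene_id)) {
    stop("duplicate gene ids: ", paste(unique(records$gene_id[duplicated(records$gene_id)]), collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(records$sequence))
  # strip initiator codon and terminal stop before bulk codon counting
  start <- if (count_start_codon) 1L else 4L
  width <- Biostrings::width(seqs)
  last <- as.character(Biostrings::subseq(seqs, width - 2L, width))
  end <- ifelse(last %in% genetic_code$stop_codons, width - 3L, width)
  trimmed <- Biostrings::subseq(seqs, start, end)
  counts <- Biostrings::trinucleotideFrequency(trimmed, step = 3L)
  counts <- counts[, genetic_code$codons, drop = FALSE]
  storage.mode(counts) <- "integer"
  rownames(counts) <- records$gene_id
  if (any(rowSums(counts) == 0L)) stop("gene with no countable sense codons")

  coords <- NULL
  if (!is.null(metadata)) {
    stopifnot(all(c("gene_id", "chromosome", "position") %in% names(metadata)))
    idx <- match(records$gene_id, metadata$gene_id)
    if (anyNA(idx)) {
      warning(sum(is.na(idx)), " gene(s) missing from metadata; coordinates set to NA")
    }
    coords <- data.frame(
      gene_id = records$gene_id,
      chromosome = metadata$chromosome[idx],
      position = metadata$position[idx],
      stringsAsFactors = FALSE
    )
  }

  structure(
    list(
      gene_ids = records$gene_id,
      counts = counts,
      gc3 = stats::setNames(gc3_percent(counts), records$gene_id),
      coords = coords,
      genetic_code = genetic_code
    ),
    class = "codon_count_table"
  )
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(
    "<codon_count_table> ", length(x$gene_ids), " genes x ", ncol(x$counts),
    " codons (", x$genetic_code$code_name, " code); median GC3 ",
    sprintf("%.3f", stats::median(x$gc3)),
    if (is.null(x$coords)) "; no coordinates" else "; with coordinates", "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a codon count table and its GC3 values to TSV
#'
#' @param table A `codon_count_table`.
#' @param path Output TSV path (`gene_id`, 61 codon columns, `gc3`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(gene_id = table$gene_ids, table$counts,
                   gc3 = unname(table$gc3), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
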