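# Temporal alignments: aligned sequences with per-sample time-layer labels
# and ages in generations, plus FASTA/TSV I/O and missing-data handling.

#' Construct a temporal alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences over
#'   the alphabet A, C, G, T, N, `-` (names are sample ids), or a character
#'   matrix with one row per sample.
#' @param meta Data frame with columns `sample_id`, `layer`,
#'   `age_generations`; every sequence must be assigned to exactly one layer.
#' @return A `temporal_alignment`: list with `seq` (named character vector)
#'   and `meta` (tibble, one row per sequence, in sequence order).
#' @export
temporal_alignment <- function(seqs, meta) {
  if (is.matrix(seqs)) {
    nm <- rownames(seqs)
    seqs <- apply(seqs, 1, paste, collapse = "")
    names(seqs) <- nm
  }
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  meta <- tibble::as_tibble(meta)
  req <- c("sample_id", "layer", "age_generations")
  if (!all(req %in% names(meta))) {
    stop("meta must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  miss <- setdiff(names(seqs), meta$sample_id)
  extra <- setdiff(meta$sample_id, names(seqs))
  if (length(miss) || length(extra)) {
    stop("sequence ids and metadata ids do not match; missing from metadata: ",
         paste(utils::head(miss, 5), collapse = ", "),
         "; missing from sequences: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(names(seqs), meta$sample_id), req]
  structure(list(seq = seqs, meta = meta), class = "temporal_alignment")
}

#' @export
print.temporal_alignment <- function(x, ...) {
  tab <- table(x$meta$layer)
  cat("<temporal_alignment>", length(x$seq), "sequences x",
      nchar(x$seq[1]), "sites;",
      paste(tab, names(tab), collapse = ", "), "\n")
  invisible(x)
}

n_sites <- function(aln) nchar(aln$seq[[1]])

# character matrix view (rows = samples)
aln_matrix <- function(aln) {
  mat <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
                nrow = length(aln$seq), byrow = TRUE)
  rownames(mat) <- names(aln$seq)
  mat
}

# restrict to one layer (keeps all columns)
subset_layer <- function(aln, layer) {
  keep <- aln$meta$layer == layer
  if (!any(keep)) stop("no sequences in layer '", layer, "'", call. = FALSE)
  temporal_alignment(aln$seq[keep], aln$meta[keep, ])
}

#' Alignment layers in increasing age order
#'
#' @param aln A `temporal_alignment`.
#' @return Tibble with columns `layer`, `age_generations`, `n`.
#' @export
alignment_layers <- function(aln) {
  aln$meta |>
    dplyr::count(.data$layer, .data$age_generations, name = "n") |>
    dplyr::arrange(.data$age_generations) |>
    dplyr::select("layer", age_generations = "age_generations", "n")
}

#' Columns usable under a missing-data policy
#'
#' Under `complete_deletion` (the default, mirroring the common DnaSP
#' setting) any column containing an undetermined base (`N`) or gap (`-`) is
#' removed before statistics are computed. Under `pairwise` all columns are
#' kept and missing data are handled per comparison downstream.
#'
#' @param aln A `temporal_alignment` (or character matrix).
#' @param policy `"complete_deletion"` or `"pairwise"`.
#' @return Integer vector of retained column indices.
#' @export
effective_columns <- function(aln, policy = c("complete_deletion", "pairwise")) {
  policy <- match.arg(policy)
  mat <- if (is.matrix(aln)) aln else aln_matrix(aln)
  if (policy == "pairwise") return(seq_len(ncol(mat)))
  keep <- which(colSums(mat == "N" | mat == "-") == 0)
  if (length(keep) == 0) {
    stop("no columns survive complete deletion", call. = FALSE)
  }
  keep
}

#' Read a temporal alignment from FASTA + metadata TSV
#'
#' The metadata table must have columns `sample_id`, `layer`,
#' `age_generations`, and its ids must match the FASTA ids exactly (strict
#' join; any mismatch is an error naming the offending ids).
#'
#' @param fasta Path to a FASTA file.
#' @param meta Path to a tab-separated metadata file.
#' @return A [temporal_alignment()].
#' @export
read_temporal_alignment <- function(fasta, meta) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta, call. = FALSE)
  if (!file.exists(meta)) stop("metadata file not found: ", meta, call. = FALSE)
  dna <- Biostrings::readDNAStringSet(fasta)
  seqs <- as.character(dna)
  md <- readr::read_tsv(meta, show_col_types = FALSE)
  temporal_alignment(seqs, md)
}

#' Write a temporal alignment to FASTA + metadata TSV
#'
#' @param aln A `temporal_alignment`.
#' @param fasta,meta Output paths.
#' @return Invisibly, the input alignment.
#' @export
write_temporal_alignment <- function(aln, fasta, meta) {
  dna <- Biostrings::DNAStringSet(aln$seq)
  Biostrings::writeXStringSet(dna, fasta)
  readr::write_tsv(aln$meta, meta)
  invisible(aln)
}
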