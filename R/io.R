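# File I/O: FASTA via Biostrings, GFF3 via rtracklayer, plus small TSV/JSON
# writers shared by the pipeline.

#' Read a FASTA file into a tibble
#'
#' @param path FASTA path (nucleotide or amino acid; parsed as plain
#'   records).
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(
    id = vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1),
    sequence = toupper(as.character(x))
  )
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param type "AA" or "DNA" (controls the Biostrings container used).
#' @param width Line-wrap width (default 60 columns).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA"), width = 60) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' @param path GFF3 path.
#' @return A tibble of annotated genes: `gene_id`, `scaffold_id`, `start`,
#'   `end` (1-based, closed), `strand`, `type`, `product`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  get_chr <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  }
  tibble(
    gene_id = get_chr("ID"),
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = get_chr("type"),
    product = get_chr("product")
  )
}

#' Write gene annotation to GFF3
#'
#' @param genes Tibble with columns `gene_id`, `scaffold_id`, `start`,
#'   `end`, `strand`, and optionally `type` (default "gene") and `product`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path) {
  type <- if ("type" %in% names(genes)) genes$type else rep("gene", nrow(genes))
  product <- if ("product" %in% names(genes)) genes$product else rep(NA_character_, nrow(genes))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold_id,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$product <- product
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
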