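#' Read sequences from a FASTA or FASTQ file
#'
#' Reads DNA sequences into a data frame of records. Lowercase bases are
#' uppercased; IUPAC ambiguity codes other than \code{N} are mapped to
#' \code{N} with a warning. FASTQ qualities are discarded.
#'
#' @param path Path to a FASTA (or, with \code{format = "fastq"}, FASTQ) file.
#' @param format Either \code{"fasta"} or \code{"fastq"}.
#' @return A data frame with columns \code{id}, \code{description} and
#'   \code{seq}, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a first", "acgt", ">b", "GG", "TT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = format)
  if (length(set) == 0L) stop("empty sequence file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("malformed header: empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- normalize_dna(as.character(set))
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence in ", path)
  data.frame(id = ids, description = desc, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns \code{id} and \code{seq}
#'   (optionally \code{description}).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  hdr <- records$id
  if (!is.null(records$description)) {
    has <- !is.na(records$description) & nzchar(records$description)
    hdr[has] <- paste(records$id[has], records$description[has])
  }
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- records$seq
  writeLines(out, path)
  invisible(path)
}

# uppercase and collapse non-ACGTN- characters to N (gap kept for alignments)
normalize_dna <- function(x) {
  x <- toupper(x)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained ambiguity codes; mapped to N")
    x[bad] <- gsub("[^ACGTN-]", "N", x[bad])
  }
  x
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file; all rows must have equal length.
#' @return A \code{dna_alignment}: a character matrix (one row per sequence,
#'   one column per alignment position) with sequence ids as row names.
#' @export
read_alignment <- function(path) {
  rec <- read_fasta(path)
  as_alignment(rec$seq, rec$id)
}

#' Build an alignment object from equal-length sequences
#'
#' @param seqs Character vector of equal-length (possibly gapped) sequences.
#' @param ids Sequence identifiers; defaults to names of \code{seqs}.
#' @return A \code{dna_alignment} character matrix.
#' @export
as_alignment <- function(seqs, ids = names(seqs)) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (!is.null(ids)) rownames(m) <- ids
    class(m) <- c("dna_alignment", class(m))
    return(m)
  }
  lens <- nchar(seqs)
  if (length(seqs) == 0L || any(lens < 1L)) stop("empty alignment")
  if (length(unique(lens)) != 1L)
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  m <- do.call(rbind, strsplit(normalize_dna(seqs), "", fixed = TRUE))
  rownames(m) <- ids
  class(m) <- c("dna_alignment", class(m))
  m
}

#' Write a data frame as a tab-separated table
#'
#' UTF-8, header first, floats printed with 6 significant digits.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(table, path) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.double, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    out <- formatC(signif(x, 6), format = "fg", digits = 6, flag = "#")
    out <- sub("\\.$", "", trimws(out))
    out[is.na(x)] <- NA
    out
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table written by \code{write_tsv}
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    na.strings = "NA", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stderr logger: "LEVEL timestamp message"
te_log <- function(level, ...) {
  msg <- paste0(level, " ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  message(msg)
  invisible(msg)
}

#' Packaged characterization table of the 23 Capsaspora owczarzaki TE families
#'
#' Copy numbers (with FLE/solo split for LTR retrotransposons), RNA-seq read
#' totals, identical-paralogous-copy counts, intra-element LTR identity
#' ranges, nucleotide diversity partitions and Tajima's D, as published for
#' the 23 TE families of the \emph{C. owczarzaki} draft genome.
#'
#' @return Data frame with one row per family.
#' @export
capsaspora_te_table <- function() {
  read_tsv(system.file("extdata", "capsaspora_te_families.tsv",
                       package = "telifecycle", mustWork = TRUE))
}

#' Total RNA-seq library size of the Capsaspora owczarzaki transcriptome
#'
#' @return Named numeric vector with element \code{total_rnaseq_reads}.
#' @export
capsaspora_rnaseq_library <- function() {
  tab <- read_tsv(system.file("extdata", "capsaspora_rnaseq_library.tsv",
                              package = "telifecycle", mustWork = TRUE))
  stats::setNames(tab$value, tab$metric)
}
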