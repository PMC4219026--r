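#' Genome index: ordered chromosome names and lengths
#'
#' The coordinate frame every other object refers to. Chromosome order follows
#' the construction/file order (reference-genome convention), never a
#' lexicographic sort.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths positive integer lengths (bp), same length as `chroms`.
#' @return A `genome_index` object (data.table with columns `chrom`, `length`).
#' @examples
#' gi <- genome_index(c("ch06", "ch11"), c(46e6, 53e6))
#' @export
genome_index <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    param_error("chroms and lengths differ in length")
  if (anyDuplicated(chroms))
    input_error("duplicated chromosome name: %s",
                chroms[duplicated(chroms)][1])
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    input_error("all chromosome lengths must be positive")
  gi <- data.table(chrom = chroms, length = lengths)
  setattr(gi, "class", c("genome_index", class(gi)))
  gi[]
}

#' Read a genome index from a two-column TSV
#'
#' Accepts `name<TAB>length` tables, including the first two columns of a
#' FASTA `.fai` index. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A [genome_index()].
#' @export
read_genome_index <- function(path) {
  if (!file.exists(path)) input_error("genome index file not found: %s", path)
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", select = 1:2,
          col.names = c("chrom", "length"), colClasses = list(character = 1)),
    error = function(e) parse_error("cannot parse genome index %s: %s",
                                    path, conditionMessage(e)))
  if (nrow(dt) == 0) input_error("genome index %s is empty", path)
  dt <- dt[!startsWith(chrom, "#")]
  len <- suppressWarnings(as.numeric(dt$length))
  if (anyNA(len)) parse_error("non-numeric length in genome index %s", path)
  genome_index(dt$chrom, len)
}

#' Write a genome index as TSV
#' @param index a [genome_index()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  stopifnot(inherits(index, "genome_index"))
  fwrite(as.data.table(index)[, .(chrom, length = as.integer(length))],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

chrom_length <- function(index, chrom) {
  i <- match(chrom, index$chrom)
  if (anyNA(i)) coord_error("chromosome '%s' absent from genome index",
                            chrom[is.na(i)][1])
  index$length[i]
}

# Order a SNP table by (index chromosome order, position); errors on unknown
# contigs or out-of-range positions (internal 0-based coordinates).
normalize_snps <- function(snps, index) {
  snps <- as.data.table(snps)
  bad <- setdiff(unique(snps$chrom), index$chrom)
  if (length(bad))
    coord_error("record on contig '%s' absent from genome index", bad[1])
  lens <- index$length[match(snps$chrom, index$chrom)]
  if (any(snps$pos < 0 | snps$pos >= lens))
    coord_error("SNP position outside chromosome bounds on %s",
                snps$chrom[which(snps$pos < 0 | snps$pos >= lens)[1]])
  snps[order(match(chrom, index$chrom), pos)]
}
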