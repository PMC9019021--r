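#' Define a toy genome as named contig lengths
#'
#' A genome specification is a named numeric vector of contig lengths in bp.
#' It stands in for a real assembly in all simulations and coordinate checks;
#' the default is a single 10 Mb contig, a desk-scale model on which kilobase
#' signal shapes around cut sites can be studied without megabase arrays.
#'
#' @param contigs named numeric vector, contig name -> length in bp.
#' @return validated named numeric vector of mode double.
#' @examples
#' genome_spec(c(chr1 = 1e7))
#' @export
genome_spec <- function(contigs = c(sim1 = 1e7)) {
  if (is.null(names(contigs)) || any(!nzchar(names(contigs))))
    stop("every contig must be named")
  if (anyDuplicated(names(contigs)))
    stop("contig names must be unique")
  if (any(!is.finite(contigs)) || any(contigs <= 0))
    stop("contig lengths must be positive and finite")
  storage.mode(contigs) <- "double"
  contigs
}

## coerce seqlengths of a GRanges-bearing object to a genome_spec
genome_of <- function(x) {
  sl <- seqlengths(x)
  if (any(is.na(sl)))
    stop("object carries no seqlengths; supply a genome_spec")
  genome_spec(sl)
}

as_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
}
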