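## Hexamer scanning upstream of first-gene polyadenylation sites. Plant
## polyadenylation is driven by loose, redundant elements rather than a
## single AAUAAA: near-upstream elements (NUE, AAUAAA-like hexamers) and
## cleavage elements (CE) near the cleavage site. The scan window runs from
## 150 nt upstream of the polyA site (or from the IS-intron donor when that
## is closer) up to the base before the polyA site, in transcription
## direction.

#' Build a NUE/CE hexamer dictionary
#'
#' @param nue,ce Character vectors of 6-mers over ACGT (DNA alphabet,
#'   upper-cased on input).
#' @return An object of class `hexamer_dictionary` with elements `nue`, `ce`.
#' @export
hexamer_dictionary <- function(nue, ce) {
  chk <- function(x, what) {
    x <- toupper(x)
    if (any(nchar(x) != 6L) || any(grepl("[^ACGT]", x)))
      stop(what, " hexamers must be 6-mers over ACGT")
    unique(x)
  }
  structure(list(nue = chk(nue, "NUE"), ce = chk(ce, "CE")),
            class = "hexamer_dictionary")
}

#' Read a one-hexamer-per-line dictionary file
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Plain-text file.
#' @return Character vector of upper-case hexamers.
#' @export
read_hexamer_file <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  toupper(x)
}

#' Default NUE/CE hexamer dictionary
#'
#' Literature-flavored, user-overridable defaults shipped as editable text
#' files under `inst/extdata/` (`nue_hexamers_default.txt`,
#' `ce_hexamers_default.txt`): AAUAAA (as DNA, AATAAA) plus common
#' single-substitution NUE variants, and a YA-centered, U-rich CE set. These
#' are synthetic stand-ins for the published element compilations, not a
#' reproduction of them; analyses meant to be compared across studies should
#' supply explicit dictionaries.
#'
#' @return A [hexamer_dictionary].
#' @export
default_hexamer_dictionary <- function() {
  hexamer_dictionary(
    nue = read_hexamer_file(system.file("extdata", "nue_hexamers_default.txt",
                                        package = "readthroughr", mustWork = TRUE)),
    ce = read_hexamer_file(system.file("extdata", "ce_hexamers_default.txt",
                                       package = "readthroughr", mustWork = TRUE)))
}

#' Build the scan window upstream of a polyA site
#'
#' On the plus strand the window is `[max(polya_pos - max_len_nt, donor_pos),
#' polya_pos - 1]` (1-based closed); mirrored on the minus strand. With
#' `anchor = "donor"` the window always extends to the donor site even when
#' that is more than `max_len_nt` upstream.
#'
#' @param chrom Chromosome name.
#' @param polya_pos 1-based position of the polyA site (last transcribed
#'   base); the window ends immediately upstream of it.
#' @param strand `"+"` or `"-"`.
#' @param donor_pos Optional 1-based IS-intron donor position (first intron
#'   base); must be upstream of `polya_pos` in transcription direction.
#' @param max_len_nt Maximum window length (default 150).
#' @param anchor `"capped"` (default: never longer than `max_len_nt`) or
#'   `"donor"` (extend to the donor site when given).
#' @return A width >= 1 [GenomicRanges::GRanges] of length 1.
#' @export
build_scan_window <- function(chrom, polya_pos, strand, donor_pos = NULL,
                              max_len_nt = 150L, anchor = c("capped", "donor")) {
  anchor <- match.arg(anchor)
  stopifnot_scalar_count(max_len_nt, "max_len_nt")
  minus <- is_minus(strand)
  if (!is.null(donor_pos)) {
    downstream <- if (minus) donor_pos <= polya_pos else donor_pos >= polya_pos
    if (downstream)
      stop("donor_pos is not upstream of polya_pos: inconsistent locus")
  }
  if (!minus) {
    lo <- polya_pos - max_len_nt
    if (!is.null(donor_pos)) lo <- if (anchor == "donor") donor_pos else max(lo, donor_pos)
    hi <- polya_pos - 1L
  } else {
    lo <- polya_pos + 1L
    hi <- polya_pos + max_len_nt
    if (!is.null(donor_pos)) hi <- if (anchor == "donor") donor_pos else min(hi, donor_pos)
  }
  if (lo > hi) stop("zero-length scan window")
  GRanges(chrom, IRanges::IRanges(max(lo, 1L), hi), strand = strand)
}

#' Scan a window for NUE and CE hexamers
#'
#' Every overlapping 6-mer of the window's transcription-direction sequence
#' is tested against both dictionary sets (via [Biostrings::matchPDict()]);
#' overlapping hits are reported individually. Positions containing `N`
#' never match.
#'
#' @param window Length-1 GRanges from [build_scan_window()].
#' @param genome A [Biostrings::DNAStringSet] keyed by chromosome.
#' @param dict A [hexamer_dictionary].
#' @param locus_id Optional label carried into the result.
#' @return A list of class `signal_scan`: `locus_id`, `window`, `nue_hits`
#'   and `ce_hits` (data.frames with `hexamer` and 1-based
#'   transcription-direction `offset`), `has_nue`, `has_ce`.
#' @export
scan_hexamers <- function(window, genome, dict, locus_id = NA_character_) {
  stopifnot(is(dict, "hexamer_dictionary"), length(window) == 1L)
  chrom <- as.character(seqnames(window))
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (start(window) < 1L || end(window) > length(genome[[chrom]]))
    stop("window outside sequence bounds")
  s <- Biostrings::subseq(genome[[chrom]], start(window), end(window))
  if (as.character(strand(window)) == "-") s <- Biostrings::reverseComplement(s)

  scan_set <- function(set) {
    if (length(set) == 0L || length(s) < 6L)
      return(data.frame(hexamer = character(), offset = integer(),
                        stringsAsFactors = FALSE))
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(set))
    m <- Biostrings::matchPDict(pd, s)
    hits <- do.call(rbind, lapply(seq_along(m), function(i) {
      if (length(m[[i]]) == 0L) return(NULL)
      data.frame(hexamer = set[i], offset = start(m[[i]]),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(hits))
      return(data.frame(hexamer = character(), offset = integer(),
                        stringsAsFactors = FALSE))
    hits[order(hits$offset, hits$hexamer), , drop = FALSE]
  }
  nue_hits <- scan_set(dict$nue)
  ce_hits <- scan_set(dict$ce)
  structure(list(locus_id = locus_id, window = window,
                 nue_hits = nue_hits, ce_hits = ce_hits,
                 has_nue = nrow(nue_hits) > 0L, has_ce = nrow(ce_hits) > 0L),
            class = "signal_scan")
}

#' @export
print.signal_scan <- function(x, ...) {
  cat(sprintf("signal_scan %s: window %s:%d-%d(%s), %d NUE hit(s), %d CE hit(s)\n",
              x$locus_id, as.character(seqnames(x$window)), start(x$window),
              end(x$window), as.character(strand(x$window)),
              nrow(x$nue_hits), nrow(x$ce_hits)))
  invisible(x)
}
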