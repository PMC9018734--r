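#' Reference locus
#'
#' A locus is a named reference sequence on which all design and prediction
#' coordinates live. Coordinates throughout the package are 0-based,
#' half-open intervals on the plus strand of this sequence.
#'
#' @param name Character label for the locus.
#' @param sequence DNA string over `{A,C,G,T,N}` (case-insensitive input,
#'   stored upper case).
#' @param origin_offset Integer genomic offset of position 0 (informational
#'   only; never enters any computation).
#' @return An object of class `wtpe_locus` with fields `name`, `sequence`
#'   and `origin_offset`.
#' @examples
#' locus("toy", "ACGTACGTACGT")
#' @export
locus <- function(name, sequence, origin_offset = 0L) {
  sequence <- toupper(sequence)
  check_dna(sequence, allow_n = TRUE, what = "locus sequence")
  if (nchar(sequence) == 0L) stop("locus sequence must be non-empty")
  structure(
    list(name = as.character(name), sequence = sequence,
         origin_offset = as.integer(origin_offset)),
    class = "wtpe_locus"
  )
}

#' @export
print.wtpe_locus <- function(x, ...) {
  cat(sprintf("<wtpe_locus> %s: %d bp (offset %d)\n",
              x$name, nchar(x$sequence), x$origin_offset))
  invisible(x)
}

#' Read loci from a FASTA file
#'
#' @param path Path to a (multi-record) FASTA file; record ids become locus
#'   names.
#' @return Named list of [locus()] objects.
#' @export
read_loci <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  out <- lapply(seq_along(ss), function(i) locus(nm[i], as.character(ss[[i]])))
  names(out) <- nm
  out
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick reverse complement; `N` maps to `N`. Input restricted to
#' `{A,C,G,T,N}`.
#'
#' @param seq DNA string.
#' @return The reverse complement, as a character string.
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(seq) {
  check_dna(toupper(seq), allow_n = TRUE, what = "seq")
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Format a half-open interval
#'
#' Standard interval notation used in package outputs:
#' `name:start-end(strand)`, 0-based half-open.
#'
#' @param name Sequence name.
#' @param start,end Integer 0-based half-open bounds.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
format_interval <- function(name, start, end, strand = "+") {
  sprintf("%s:%d-%d(%s)", name, start, end, strand)
}

#' Construct a SpCas9 spacer site from its protospacer interval
#'
#' A spacer site is a 20-nt protospacer with an NGG PAM. On the plus strand
#' the PAM occupies the 3 nt after the protospacer interval; on the minus
#' strand, the 3 nt before it (plus-strand coordinates). The blunt
#' double-strand break falls 3 nt 5' of the PAM on the protospacer strand:
#' `start + 17` for plus-strand sites, `start + 3` for minus-strand sites.
#'
#' @param locus A [locus()].
#' @param start 0-based start of the 20-nt protospacer interval on the plus
#'   strand.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `wtpe_site` with fields `locus_name`,
#'   `protospacer`, `pam` (both 5'->3' on the site strand), `strand`,
#'   `start`, `end`, and `cut` (blunt cut position, plus strand).
#' @examples
#' loc <- locus("toy", "TTTTACGTACGTACGTACGTACGTTGGTTTT")
#' spacer_site(loc, 4, "+")
#' @export
spacer_site <- function(locus, start, strand = c("+", "-")) {
  strand <- match.arg(strand)
  stopifnot(inherits(locus, "wtpe_locus"))
  start <- as.integer(start)
  L <- nchar(locus$sequence)
  end <- start + 20L
  if (strand == "+") {
    if (start < 0L || end + 3L > L) stop("protospacer+PAM out of locus bounds")
    proto <- substr0(locus$sequence, start, end)
    pam <- substr0(locus$sequence, end, end + 3L)
    cut <- start + 17L
  } else {
    if (start - 3L < 0L || end > L) stop("protospacer+PAM out of locus bounds")
    proto <- revcomp(substr0(locus$sequence, start, end))
    pam <- revcomp(substr0(locus$sequence, start - 3L, start))
    cut <- start + 3L
  }
  if (!grepl("^[ACGT]GG$", pam))
    stop("PAM at this position is ", pam, ", not NGG")
  if (grepl("N", proto, fixed = TRUE))
    stop("protospacer contains N")
  if (cut <= 0L || cut >= L) stop("cut position not strictly inside locus")
  structure(
    list(locus_name = locus$name, protospacer = proto, pam = pam,
         strand = strand, start = start, end = end, cut = cut),
    class = "wtpe_site"
  )
}

#' @export
print.wtpe_site <- function(x, ...) {
  cat(sprintf("<wtpe_site> %s %s PAM=%s cut=%d\n",
              format_interval(x$locus_name, x$start, x$end, x$strand),
              x$protospacer, x$pam, x$cut))
  invisible(x)
}

#' Blunt cut position of a spacer site
#'
#' Recomputes the SpCas9 blunt DSB coordinate from the protospacer interval:
#' between protospacer positions 17 and 18, i.e. 3 nt 5' of the PAM.
#'
#' @param site A [spacer_site()].
#' @return Integer plus-strand cut coordinate.
#' @export
cut_position_of <- function(site) {
  stopifnot(inherits(site, "wtpe_site"))
  if (site$strand == "+") site$start + 17L else site$start + 3L
}

#' Find all SpCas9 spacer sites in a region
#'
#' Scans both strands of `region` for 20-nt protospacers followed by an NGG
#' PAM. `N` in the reference never matches a protospacer or PAM position.
#'
#' @param locus A [locus()].
#' @param region Length-2 integer vector, 0-based half-open, defaulting to
#'   the whole locus. Must be at least 23 nt long.
#' @return List of [spacer_site()] objects sorted by cut position, then
#'   strand (`+` before `-`).
#' @export
find_spacer_sites <- function(locus, region = NULL) {
  stopifnot(inherits(locus, "wtpe_locus"))
  L <- nchar(locus$sequence)
  if (is.null(region)) region <- c(0L, L)
  region <- as.integer(region)
  if (region[1] < 0L || region[2] > L || region[1] > region[2])
    stop("region out of locus bounds")
  if (diff(region) < 23L) stop("region must be at least 23 nt")
  sub <- substr0(locus$sequence, region[1], region[2])

  starts_of <- function(pattern) {
    m <- gregexpr(pattern, sub, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L + region[1]
  }
  # plus: protospacer(20) + N + GG, all non-N
  plus <- starts_of("(?=[ACGT]{21}GG)")
  # minus: CCN + protospacer(20) on the plus strand
  minus <- starts_of("(?=CC[ACGT]{21})")

  sites <- c(
    lapply(plus, function(s) spacer_site(locus, s, "+")),
    lapply(minus, function(s) spacer_site(locus, s + 3L, "-"))
  )
  if (length(sites) == 0L) return(sites)
  ord <- order(vapply(sites, `[[`, integer(1), "cut"),
               match(vapply(sites, `[[`, character(1), "strand"), c("+", "-")))
  sites[ord]
}
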