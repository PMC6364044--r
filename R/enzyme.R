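#' Restriction enzyme definition
#'
#' Construct a restriction enzyme from its recognition site and cut offset.
#' Only palindromic sites over the ACGT alphabet are accepted: site scanning
#' is performed on the top strand only, which is exact if and only if the
#' site equals its own reverse complement. The cut offset is the 0-based
#' position on the top strand after which the enzyme cuts (e.g. HindIII
#' A^AGCTT has offset 1).
#'
#' @param name Enzyme name.
#' @param site Recognition site, ACGT only, palindromic.
#' @param cut_offset Integer in `[0, nchar(site)/2]`.
#' @return An object of class `restriction_enzyme` with fields `name`,
#'   `site`, `cut_offset`.
#' @examples
#' restriction_enzyme("HindIII", "AAGCTT", 1)
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L)
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) {
    stop("recognition site must contain only A/C/G/T (no ambiguity codes): ", site)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (!identical(site, rc)) {
    stop("recognition site must be palindromic (its own reverse complement): ", site)
  }
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site) %/% 2L) {
    stop("cut_offset must lie in [0, ", nchar(site) %/% 2L, "] for site ", site)
  }
  structure(list(name = name, site = site, cut_offset = cut_offset),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  marked <- paste0(substr(x$site, 1L, x$cut_offset), "^",
                   substr(x$site, x$cut_offset + 1L, nchar(x$site)))
  cat(sprintf("<restriction_enzyme> %s  %s\n", x$name, marked))
  invisible(x)
}

# Built-in enzymes used throughout Hi-C protocols.
.builtin_enzymes <- function() {
  list(
    HindIII = restriction_enzyme("HindIII", "AAGCTT", 1L),
    NcoI    = restriction_enzyme("NcoI",    "CCATGG", 1L),
    DpnII   = restriction_enzyme("DpnII",   "GATC",   0L),
    MboI    = restriction_enzyme("MboI",    "GATC",   0L)
  )
}

#' Look up a built-in enzyme by name
#'
#' HindIII, NcoI, DpnII and MboI are predefined. Passing a
#' `restriction_enzyme` object returns it unchanged.
#'
#' @param enzyme Enzyme name or `restriction_enzyme` object.
#' @return A `restriction_enzyme`.
#' @export
get_enzyme <- function(enzyme) {
  if (inherits(enzyme, "restriction_enzyme")) return(enzyme)
  tab <- .builtin_enzymes()
  hit <- tab[[as.character(enzyme)]]
  if (is.null(hit)) {
    stop("unknown enzyme '", enzyme, "'; built-ins are ",
         paste(names(tab), collapse = ", "),
         ". Use restriction_enzyme() for a custom cutter.")
  }
  hit
}

#' Reconstructed ligation junction sequence
#'
#' The Hi-C protocol fills in the 5' overhangs left by the cutter and
#' blunt-ligates the ends. The resulting chimeric sequence is the site
#' prefix up to the bottom-strand cut, followed by the site suffix from the
#' top-strand cut: `site[1..len-cut_offset] + site[cut_offset+1..len]`, of
#' length `2*(len(site) - cut_offset)`. Finding this sequence inside a read
#' marks read-through into the ligated partner fragment.
#'
#' @param enzyme Enzyme name or `restriction_enzyme`.
#' @return Junction DNA string.
#' @examples
#' make_ligation_junction("HindIII")  # "AAGCTAGCTT"
#' make_ligation_junction("MboI")     # "GATCGATC"
#' @export
make_ligation_junction <- function(enzyme) {
  enzyme <- get_enzyme(enzyme)
  len <- nchar(enzyme$site)
  paste0(substr(enzyme$site, 1L, len - enzyme$cut_offset),
         substr(enzyme$site, enzyme$cut_offset + 1L, len))
}
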