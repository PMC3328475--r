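#' Define a blunt-end restriction enzyme
#'
#' An enzyme is described by its recognition sequence and the (blunt) cut
#' position within that sequence. The bases of the site downstream of the
#' cut form the *residual tag* that every properly constructed library read
#' begins with (e.g. `"CT"` for AluI, which cuts `AG^CT`).
#'
#' Recognition sites may contain IUPAC ambiguity codes (some blunt cutters,
#' e.g. RseI `CAYNN^NNRTG`, have degenerate sites); ambiguity codes act as
#' wildcards during digestion, but an `N` in the *genome* never matches.
#'
#' @param name Enzyme name, e.g. `"AluI"`.
#' @param recognition_site Recognition sequence, 5'->3', IUPAC letters.
#' @param cut_offset Integer in `[0, nchar(site)]`: number of site bases 5'
#'   of the cut. AluI (`AG^CT`) has `cut_offset = 2`.
#' @return An object of class `"enzyme"`.
#' @examples
#' alui <- enzyme("AluI", "AGCT", 2)
#' residual_tag(alui)  # "CT"
#' @export
enzyme <- function(name, recognition_site, cut_offset) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  site <- toupper(as.character(recognition_site))
  if (length(site) != 1L || !nzchar(site))
    stop("recognition_site must be a non-empty DNA string", call. = FALSE)
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", site))
    stop("recognition_site contains non-IUPAC letters: ", site, call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset must lie in [0, nchar(recognition_site)]", call. = FALSE)
  structure(
    list(name = name, recognition_site = site, cut_offset = cut_offset),
    class = "enzyme"
  )
}

#' @export
print.enzyme <- function(x, ...) {
  cat(sprintf("<enzyme> %s  %s^%s\n", x$name,
              substr(x$recognition_site, 1L, x$cut_offset),
              substr(x$recognition_site, x$cut_offset + 1L,
                     nchar(x$recognition_site))))
  invisible(x)
}

#' Residual tag of an enzyme
#'
#' The site bases 3' of the blunt cut, i.e. the prefix that reads from a
#' properly ligated fragment end carry.
#'
#' @param enz An [enzyme()].
#' @return A character scalar (possibly empty when the enzyme cuts at the
#'   site boundary).
#' @export
residual_tag <- function(enz) {
  stopifnot(inherits(enz, "enzyme"))
  substr(enz$recognition_site, enz$cut_offset + 1L,
         nchar(enz$recognition_site))
}

site_is_degenerate <- function(enz) {
  grepl("[^ACGT]", enz$recognition_site)
}

site_is_palindromic <- function(enz) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(enz$recognition_site)))
  identical(rc, enz$recognition_site)
}

#' Blunt-end enzymes screened for library construction
#'
#' The four blunt cutters evaluated for reduced-representation library
#' design: AluI (`AG^CT`), DpnI (`GA^TC`), RsaI (`GT^AC`) and RseI
#' (`CAYNN^NNRTG`). AluI is the default library enzyme; its residual tag is
#' `"CT"`.
#'
#' @return A named list of [enzyme()] objects.
#' @export
blunt_enzymes <- function() {
  list(
    AluI = enzyme("AluI", "AGCT", 2L),
    DpnI = enzyme("DpnI", "GATC", 2L),
    RsaI = enzyme("RsaI", "GTAC", 2L),
    RseI = enzyme("RseI", "CAYNNNNRTG", 5L)
  )
}
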