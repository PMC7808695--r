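#' SNP site panel with reference-individual genotypes
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `is_transversion`.
#' @param geno integer matrix (individuals x sites) of diploid alt-allele
#'   dosages in `{0, 1, 2, NA}`, rownames = individual ids.
#' @param labels data.frame mapping `individual` to `population` (extra
#'   columns such as a median calibrated age are kept as-is), or NULL.
#' @param x_sites optional data.frame of X-chromosome sites with columns
#'   `pos`, `ref`, `alt`, `f` (population alt-allele frequency; `f = 0` marks
#'   monomorphic control sites) used for male X contamination estimation.
#' @return An object of class `site_panel`.
#' @export
site_panel <- function(sites, geno, labels = NULL, x_sites = NULL) {
  stopifnot(is.data.frame(sites),
            all(c("contig", "pos", "ref", "alt", "is_transversion") %in%
                  names(sites)))
  if (!is.null(geno)) {
    stopifnot(is.matrix(geno), ncol(geno) == nrow(sites))
    if (any(!is.na(geno) & !(geno %in% 0:2))) {
      stop("site_panel: dosages must be 0, 1, 2 or NA")
    }
  }
  structure(list(sites = sites, geno = geno, labels = labels,
                 x_sites = x_sites),
            class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat(sprintf("<site_panel> %d sites, %d individuals%s\n", nrow(x$sites),
              if (is.null(x$geno)) 0L else nrow(x$geno),
              if (is.null(x$labels)) "" else
                sprintf(" in %d population(s)",
                        length(unique(x$labels$population)))))
  invisible(x)
}
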