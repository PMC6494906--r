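#' The 19-gene GABA-A receptor subunit panel
#'
#' A `GenePanel` is an ordered set of gene symbols together with a subunit
#' family tag per gene and the membership of each gene in one of the
#' stoichiometric family sums: Sigma-alpha (the six alpha-subunit genes),
#' Sigma-beta (the three beta genes plus theta, which occupies a beta-like
#' position in the pentamer), Sigma-chi (the "odd-position" subunits: the
#' three gammas, delta, epsilon and pi), or `excluded` (the three rho genes,
#' which form homomeric receptors and are left out of the 2:2:1 accounting).
#'
#' @param symbols character vector of unique gene symbols.
#' @param family named character vector mapping each symbol to a family tag.
#' @param sum_membership named character vector mapping each symbol to one of
#'   `"SigmaAlpha"`, `"SigmaBeta"`, `"SigmaChi"`, `"excluded"`.
#' @return An object of class `GenePanel`.
#' @export
gene_panel <- function(symbols, family, sum_membership) {
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols)) stop("panel symbols must be unique")
  if (!all(symbols %in% names(family)))
    stop("every symbol needs a family tag")
  if (!all(symbols %in% names(sum_membership)))
    stop("every symbol needs a sum membership")
  ok <- c("SigmaAlpha", "SigmaBeta", "SigmaChi", "excluded")
  bad <- setdiff(unique(sum_membership[symbols]), ok)
  if (length(bad))
    stop("unknown sum membership: ", paste(bad, collapse = ", "))
  structure(
    list(symbols = symbols,
         family = family[symbols],
         sum_membership = sum_membership[symbols]),
    class = "GenePanel")
}

#' Default GABA-A receptor gene panel
#'
#' The 19 human GABA-A receptor subunit genes in fixed order:
#' GABRA1..GABRA6, GABRB1..GABRB3, GABRD, GABRE, GABRG1..GABRG3, GABRP,
#' GABRQ, GABRR1..GABRR3.
#'
#' @return A `GenePanel` with 19 genes.
#' @examples
#' p <- gaba_panel()
#' length(p$symbols)  # 19
#' @export
gaba_panel <- function() {
  symbols <- c(paste0("GABRA", 1:6), paste0("GABRB", 1:3),
               "GABRD", "GABRE", paste0("GABRG", 1:3),
               "GABRP", "GABRQ", paste0("GABRR", 1:3))
  family <- c(rep("alpha", 6), rep("beta", 3), "delta", "epsilon",
              rep("gamma", 3), "pi", "theta", rep("rho", 3))
  names(family) <- symbols
  membership <- c(rep("SigmaAlpha", 6),           # GABRA1..6
                  rep("SigmaBeta", 3),            # GABRB1..3
                  "SigmaChi", "SigmaChi",         # GABRD, GABRE
                  rep("SigmaChi", 3),             # GABRG1..3
                  "SigmaChi",                     # GABRP
                  "SigmaBeta",                    # GABRQ (theta)
                  rep("excluded", 3))             # GABRR1..3
  names(membership) <- symbols
  gene_panel(symbols, family, membership)
}

#' @export
print.GenePanel <- function(x, ...) {
  cat("GenePanel:", length(x$symbols), "genes\n")
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}
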