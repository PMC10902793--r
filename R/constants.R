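# Physical constants (SI) used to derive the Bjerrum length
.const <- list(
  e = 1.602176634e-19,      # elementary charge, C
  eps0 = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB = 1.380649e-23,        # Boltzmann constant, J/K
  avogadro = 6.02214076e23    # Avogadro number, 1/mol
)

#' Molecular weights of the standard amino acids
#'
#' Free amino-acid molecular weights in g/mol, used by the coarse-graining
#' diameter rule \eqn{\sigma = (6 M_W / \pi \rho)^{1/3}}.
#'
#' @param extra optional named numeric vector of additional 3-letter codes.
#' @return named numeric vector keyed by 3-letter residue code.
#' @export
residue_weights <- function(extra = NULL) {
  w <- c(
    GLY = 75.07, ALA = 89.09, SER = 105.09, PRO = 115.13, VAL = 117.15,
    THR = 119.12, CYS = 121.16, LEU = 131.17, ILE = 131.17, ASN = 132.12,
    ASP = 133.10, GLN = 146.15, LYS = 146.19, GLU = 147.13, MET = 149.21,
    HIS = 155.15, PHE = 165.19, ARG = 174.20, TYR = 181.19, TRP = 204.23
  )
  if (!is.null(extra)) w[names(extra)] <- extra
  w
}

#' Default intrinsic pKa values for titratable residues
#'
#' Standard literature values for the titratable side chains (and the chain
#' termini, available under the codes `NTR`/`CTR` for users who model them
#' explicitly).  Glutamine is treated as non-titratable.  All values can be
#' replaced via [read_pka_table()].
#'
#' @return tibble with columns `code` and `pka`.
#' @export
default_pka_table <- function() {
  tibble(
    code = c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG", "NTR", "CTR"),
    pka = c(4.0, 4.4, 6.3, 10.8, 9.6, 10.4, 12.0, 7.5, 3.67)
  )
}

#' Default protonation charge rules
#'
#' Charge (in units of e) carried by a titratable site in its protonated and
#' deprotonated forms: acids are 0 / -1, bases are +1 / 0.
#'
#' @return tibble with columns `code`, `q_protonated`, `q_deprotonated`.
#' @export
default_charge_rules <- function() {
  acids <- c("ASP", "GLU", "CYS", "TYR", "CTR")
  bases <- c("HIS", "LYS", "ARG", "NTR")
  tibble(
    code = c(acids, bases),
    q_protonated = c(rep(0, length(acids)), rep(1, length(bases))),
    q_deprotonated = c(rep(-1, length(acids)), rep(0, length(bases)))
  )
}

#' Read a pKa table from a two-column text file
#'
#' Expects whitespace-separated `code pka` rows; lines starting with `#` are
#' comments.
#'
#' @param file path to the table.
#' @return tibble with columns `code` and `pka`.
#' @export
read_pka_table <- function(file) {
  df <- read.table(file, header = FALSE, comment.char = "#",
                   col.names = c("code", "pka"),
                   colClasses = c("character", "numeric"))
  as_tibble(df)
}
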