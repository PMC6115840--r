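#' Amino-acid z-scale descriptor table
#'
#' Five physiochemical descriptors per amino acid: z1 (hydrophobicity),
#' z2 (steric bulk), z3 (polarity), z4 and z5 (electronic effects), from
#' the extended principal-property scales of Sandberg et al. (1998,
#' J. Med. Chem. 41:2481-2491) derived from 26 measured physicochemical
#' properties of the coded amino acids.  The same values ship as a
#' plain-text table in `inst/extdata/zscales_sandberg1998.tsv`.
#'
#' @return A 20 x 5 numeric matrix, rows named by one-letter amino-acid
#'   code, columns `z1`..`z5`.
#' @export
#' @examples
#' z_scales()["A", ]
z_scales <- function() {
  vals <- c(
    A =  c( 0.24, -2.32,  0.60, -0.14,  1.30),
    R =  c( 3.52,  2.50, -3.50,  1.99, -0.17),
    N =  c( 3.05,  1.62,  1.04, -1.15,  1.61),
    D =  c( 3.98,  0.93,  1.93, -2.46,  0.75),
    C =  c( 0.84, -1.67,  3.71,  0.18, -2.65),
    Q =  c( 1.75,  0.50, -1.44, -1.34,  0.66),
    E =  c( 3.11,  0.26, -0.11, -3.04, -0.25),
    G =  c( 2.05, -4.06,  0.36, -0.82, -0.38),
    H =  c( 2.47,  1.95,  0.26,  3.90,  0.09),
    I =  c(-3.89, -1.73, -1.71, -0.84,  0.26),
    L =  c(-4.28, -1.30, -1.49, -0.72,  0.84),
    K =  c( 2.29,  0.89, -2.49,  1.49,  0.31),
    M =  c(-2.85, -0.22,  0.47,  1.94, -0.98),
    F =  c(-4.22,  1.94,  1.06,  0.54, -0.62),
    P =  c(-1.66,  0.27,  1.84,  0.70,  2.00),
    S =  c( 2.39, -1.07,  1.15, -1.39,  0.67),
    T =  c( 0.75, -2.18, -1.12, -1.46, -0.40),
    W =  c(-4.36,  3.94,  0.59,  3.44, -1.59),
    Y =  c(-2.54,  2.44,  0.43,  0.04, -1.47),
    V =  c(-2.59, -2.64, -1.54, -0.85, -0.02))
  m <- matrix(vals, nrow = 20, ncol = 5, byrow = TRUE,
              dimnames = list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                                "I", "L", "K", "M", "F", "P", "S", "T", "W",
                                "Y", "V"),
                              paste0("z", 1:5)))
  m
}
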