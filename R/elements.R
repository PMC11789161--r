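# Element data tables, fixed and versioned with the package.
#
# Covalent radii (angstrom): single-bond values of Cordero et al. (2008),
# the set in common crystallographic use for bond perception.
# Scattering factors: International Tables four-Gaussian-plus-constant
# parameterization, f(s) = sum_i a_i exp(-b_i s^2) + c with s = sin(theta)/lambda.

.covalent_radii <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39,
  Cu = 1.32, Zn = 1.22, Na = 1.66, K = 2.03
)

.sfac_table <- list(
  H  = list(a = c(0.493002, 0.322912, 0.140191, 0.040810),
            b = c(10.5109, 26.1257, 3.14236, 57.7997), c = 0.003038),
  C  = list(a = c(2.3100, 1.0200, 1.5886, 0.8650),
            b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
  N  = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
            b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
  O  = list(a = c(3.0485, 2.2868, 1.5463, 0.8670),
            b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508),
  F  = list(a = c(3.5392, 2.6412, 1.5170, 1.0243),
            b = c(10.2825, 4.2944, 0.2615, 26.1476), c = 0.2776),
  P  = list(a = c(6.4345, 4.1791, 1.7800, 1.4908),
            b = c(1.9067, 27.1570, 0.5260, 68.1645), c = 1.1149),
  S  = list(a = c(6.9053, 5.2034, 1.4379, 1.5863),
            b = c(1.4679, 22.2151, 0.2536, 56.1720), c = 0.8669),
  Cl = list(a = c(11.4604, 7.1964, 6.2556, 1.6455),
            b = c(0.0104, 1.1662, 18.5194, 47.7784), c = -9.5574),
  Br = list(a = c(17.1789, 5.2358, 5.6377, 3.9851),
            b = c(2.1723, 16.5796, 0.2609, 41.4328), c = 2.9557),
  I  = list(a = c(20.1472, 18.9949, 7.5138, 2.2735),
            b = c(4.3470, 0.3814, 27.7660, 66.8776), c = 4.0712),
  Cu = list(a = c(13.3380, 7.1676, 5.6158, 1.6735),
            b = c(3.5828, 0.2470, 11.3966, 64.8126), c = 1.1910)
)

#' Covalent radius of an element
#'
#' @param element Character vector of element symbols.
#' @return Covalent radii in angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .covalent_radii[element]
  if (anyNA(r))
    stop("no covalent radius for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  unname(r)
}

# X-ray form factor f(s), s = sin(theta)/lambda in 1/angstrom
scattering_factor <- function(element, s) {
  p <- .sfac_table[[element]]
  if (is.null(p))
    stop("no scattering factor parameters for element: ", element)
  s2 <- s^2
  colSums(p$a * exp(-outer(p$b, s2))) + p$c
}
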