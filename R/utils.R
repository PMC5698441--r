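# Internal helpers shared across modules.

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3TO1 <- c(ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
            GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
            MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
            SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y")

AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# angle (degrees) at vertex b of points a-b-c
#' @noRd
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# signed torsion angle (degrees) over points p1-p2-p3-p4, in (-180, 180]
#' @noRd
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' @noRd
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @noRd
unit <- function(v) v / sqrt(sum(v^2))

# NeRF placement: coordinates of atom D bonded to C, with bond length
# |C-D| = bond, angle B-C-D = theta (deg), torsion A-B-C-D = chi (deg).
#' @noRd
place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ch),
          bond * sin(th) * sin(ch))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
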