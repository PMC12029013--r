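# Internal numerical helpers shared across modules.

# Standard atomic masses (amu) for elements common in protein/lipid systems.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, FE = 55.845, MG = 24.305, K = 39.098, CL = 35.45,
  NA. = 22.990, ZN = 65.38
)

#' Look up atomic masses by element symbol
#'
#' Unknown elements fall back to carbon mass (12.011) with a warning; this
#' only affects center-of-mass weighting, never atom counts.
#'
#' @param element character vector of element symbols (e.g. "C", "P", "FE").
#' @return numeric vector of masses in amu.
#' @keywords internal
element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."  # sodium; avoid clash with R's NA
  m <- .element_masses[key]
  if (anyNA(m)) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ", "),
            "; using carbon mass")
    m[is.na(m)] <- 12.011
  }
  unname(m)
}

# Infer an element symbol from a PDB atom name: strip leading digits, take
# the leading alphabetic run, and keep two letters only for common
# two-letter elements (FE, MG, CL, ZN); otherwise the first letter.
infer_element <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  lead <- toupper(sub("^([A-Za-z]+).*$", "\\1", stripped))
  two <- substr(lead, 1, 2)
  el <- substr(lead, 1, 1)
  is_two <- two %in% c("FE", "MG", "CL", "ZN", "BR")
  el[is_two] <- two[is_two]
  el
}

# Minimum-image displacement for orthorhombic boxes. `d` is a matrix (n x 3)
# of raw displacements; `box` a length-3 vector (Angstrom) or NULL for no
# periodicity.
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in seq_len(ncol(d))) {
    if (is.finite(box[k]) && box[k] > 0) {
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
  }
  d
}

# Largest-remainder apportionment of `n` items to fractions `p` (sums to 1).
largest_remainder <- function(p, n) {
  stopifnot(abs(sum(p) - 1) < 1e-6, n >= 0)
  raw <- p * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(p))
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, window = 3L) {
  window <- as.integer(window)
  if (window <= 1L || length(x) < 2L) return(as.numeric(x))
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Local maxima of a numeric vector with topographic prominence
# (scipy-style): for each candidate peak, walk outwards until a strictly
# higher point (or the boundary) is hit; the base on each side is the
# minimum over that stretch and the reference level is the higher of the
# two bases. Plateaus count once, at their first index. Returns a
# data.frame(index, height, prominence) sorted by decreasing prominence.
local_maxima <- function(x) {
  n <- length(x)
  if (n == 0L) return(data.frame(index = integer(), height = numeric(), prominence = numeric()))
  if (n == 1L) return(data.frame(index = 1L, height = x, prominence = x))
  cand <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || x[i - 1L] < x[i]
    right_ok <- j == n || x[j + 1L] < x[i]
    if (left_ok && right_ok) cand <- c(cand, i)
    i <- j + 1L
  }
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lo <- p
    left_min <- h
    while (lo > 1L && x[lo - 1L] <= h) {
      lo <- lo - 1L
      left_min <- min(left_min, x[lo])
    }
    hi <- p
    right_min <- h
    while (hi < n && x[hi + 1L] <= h) {
      hi <- hi + 1L
      right_min <- min(right_min, x[hi])
    }
    base <- if (lo == 1L && hi == n) min(left_min, right_min) else {
      if (lo == 1L) right_min else if (hi == n) left_min else max(left_min, right_min)
    }
    h - base
  }, numeric(1))
  out <- data.frame(index = cand, height = x[cand], prominence = prom)
  out[order(-out$prominence, out$index), , drop = FALSE]
}

# Clamp to [-1, 1] before acos to absorb rounding.
safe_acos <- function(x) acos(pmin(1, pmax(-1, x)))

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

# Unit vector, with an informative error on (near-)zero input.
unit <- function(v, tol = 1e-12) {
  nv <- sqrt(sum(v^2))
  if (nv < tol) stop("cannot normalize a (near-)zero vector")
  v / nv
}
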