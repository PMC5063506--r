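#' Parse a residue selection specification
#'
#' Selections use the compact syntax `"chain:resnum"`, `"chain:from-to"`, or
#' bare `"chain"` for a whole chain; several specs can be given as a character
#' vector or comma-separated in one string.
#'
#' @param spec Character vector of selection specs, e.g.
#'   `c("C:5", "C:10-20", "B")` or `"C:5,C:10-20,B"`.
#' @return A tibble with columns `chain`, `from`, `to` (`NA` for whole-chain).
#' @examples
#' parse_selection("C:120-129,B")
#' @export
parse_selection <- function(spec) {
  if (!is.character(spec) || length(spec) == 0) {
    stop_input("selection spec must be a non-empty character vector")
  }
  parts <- unlist(strsplit(spec, ",", fixed = TRUE))
  parts <- trimws(parts[nzchar(trimws(parts))])
  if (length(parts) == 0) stop_input("empty selection spec")
  purrr::map_dfr(parts, function(p) {
    bits <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(bits) == 1) {
      return(tibble(chain = bits[1], from = NA_integer_, to = NA_integer_))
    }
    if (length(bits) != 2) stop_input("cannot parse selection '", p, "'")
    rng <- strsplit(bits[2], "-", fixed = TRUE)[[1]]
    from <- suppressWarnings(as.integer(rng[1]))
    to <- if (length(rng) > 1) suppressWarnings(as.integer(rng[2])) else from
    if (is.na(from) || is.na(to)) stop_input("cannot parse residue range in '", p, "'")
    tibble(chain = bits[1], from = from, to = to)
  })
}

# logical mask of model rows matched by a parsed or raw selection
selection_mask <- function(model, spec) {
  sel <- if (is.data.frame(spec)) spec else parse_selection(spec)
  mask <- rep(FALSE, nrow(model))
  for (i in seq_len(nrow(sel))) {
    m <- model$chain == sel$chain[i]
    if (!is.na(sel$from[i])) {
      m <- m & model$resnum >= sel$from[i] & model$resnum <= sel$to[i]
    }
    mask <- mask | m
  }
  mask
}

# coordinates as an n x 3 matrix from a structure tibble or matrix
coords_of <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 3) stop_input("coordinate matrix must have 3 columns")
    return(x)
  }
  if (is.data.frame(x)) {
    return(cbind(x$x, x$y, x$z))
  }
  stop_input("cannot extract coordinates from object of class ", class(x)[1])
}

# minimum Euclidean distance between two atom sets (n x 3, m x 3)
min_pair_dist <- function(a, b) {
  a <- coords_of(a); b <- coords_of(b)
  if (nrow(a) == 0 || nrow(b) == 0) stop_input("empty atom selection in distance computation")
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j, vectorised over all pairs
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

# per-group (residue) minimum distance to a target atom set
group_min_dist <- function(coords, groups, target) {
  d2 <- outer(rowSums(coords^2), rowSums(target^2), "+") - 2 * tcrossprod(coords, target)
  d2 <- pmax(d2, 0)
  row_min <- sqrt(apply(d2, 1, min))
  tapply(row_min, groups, min)
}

# apply a rigid transform x -> x R^T + t
apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

rotation_xyz <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay); cz <- cos(az); sz <- sin(az)
  rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

# deterministic, seed-scoped RNG without touching global state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_input("seed must be a single integer")
  }
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- rlang::`%||%`
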