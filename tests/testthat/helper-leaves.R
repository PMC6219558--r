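# small hand-built origin tables for geometry tests: a straight vertical
# axis of the given length with origins specified as (s, side) pairs
toy_origins <- function(s, side, offset = 1) {
  tibble::tibble(
    x = ifelse(side == "left", -offset, offset),
    y = s, s = s, side = side)
}

toy_leaf <- function(s, side, length = max(s) + 10, offset = 1,
                     leaf_id = "toy") {
  list(leaf_id = leaf_id,
       axis = midvein_axis(rbind(c(0, 0), c(0, length))),
       origins = toy_origins(s, side, offset))
}

# pair-enumeration oracle for the Brunner-Munzel relative effect
p_hat_enum <- function(x, y) {
  mean(outer(x, y, `<`) + 0.5 * outer(x, y, `==`))
}

# rigid motions for invariance tests
rotate_pts <- function(m, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  t(R %*% t(m))
}
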