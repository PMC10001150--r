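# Simplex quadrature rules (barycentric weights; weights sum to 1).

quad_tet4 <- local({
  a <- 0.5854101966249685; b <- 0.1381966011250105
  list(bary = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
       w = rep(0.25, 4))   # degree 2
})

quad_tri6 <- local({
  a1 <- 0.445948490915965; b1 <- 0.108103018168070
  a2 <- 0.091576213509771; b2 <- 0.816847572980459
  list(bary = rbind(c(b1, a1, a1), c(a1, b1, a1), c(a1, a1, b1),
                    c(b2, a2, a2), c(a2, b2, a2), c(a2, a2, b2)),
       w = c(rep(0.223381589678011, 3), rep(0.109951743655322, 3)))  # degree 4
})

quad_tri3 <- list(bary = rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5)),
                  w = rep(1 / 3, 3))   # mid-edge, degree 2

# physical quadrature points for a set of cells: returns list of
# (npts x dim) coordinate matrices, one per quadrature node
simplex_quad_points <- function(vert, cell, rule) {
  nq <- nrow(rule$bary)
  lapply(seq_len(nq), function(q) {
    acc <- 0
    for (l in seq_len(ncol(cell)))
      acc <- acc + rule$bary[q, l] * vert[cell[, l], , drop = FALSE]
    acc
  })
}
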