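# shared in-code fixtures

# 8-node unit cube: one hexa solid, nodes in keyword corner order
unit_cube_mesh <- function() {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  fe_mesh(node_ids = 1:8, node_coords = coords,
          solids = data.frame(id = 1L, part = 1L, n1 = 1L, n2 = 2L, n3 = 3L,
                              n4 = 4L, n5 = 5L, n6 = 6L, n7 = 7L, n8 = 8L),
          landmark_set = c(1L, 2L, 3L, 5L))
}

unit_cube_corners <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# small non-degenerate landmark cloud (head scale, mm)
random_landmarks <- function(m, scale = 60) {
  matrix(stats::rnorm(3 * m), m, 3) * scale
}
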