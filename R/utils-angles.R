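# Angle helpers. Convention: headings in radians, counter-clockwise from +x,
# wrapped to [0, 2*pi).

wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

# Unsigned difference between two headings, in [0, pi].
unsigned_angle_diff <- function(a, b) {
  d <- abs(wrap_angle(a) - wrap_angle(b))
  pmin(d, 2 * pi - d)
}

# 2x2 counter-clockwise rotation matrix.
rotation_matrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), nrow = 2)
}

# Unit vector for a heading.
heading_vector <- function(theta) {
  cbind(cos(theta), sin(theta))
}
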