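# Analytic area of intersection between a disc and the rectangular
# window.  Disc centres always lie inside the window (pattern points
# are validated against it), so the intersection decomposes into four
# quadrant pieces, each the area of {0 <= x <= a, 0 <= y <= b,
# x^2 + y^2 <= r^2} for the distances (a, b) from the centre to the two
# relevant window edges.  The closed form lives in src/kernels.cpp;
# this wrapper recycles arguments.
disc_window_area <- function(cx, cy, r, width, height) {
  m <- max(length(cx), length(cy), length(r))
  disc_window_area_cpp(rep_len(cx, m), rep_len(cy, m), rep_len(r, m),
                       width, height)
}
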