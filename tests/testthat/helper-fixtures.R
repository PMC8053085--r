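# Small in-code fixtures shared across the test files.

# a peak list built directly from residue/shift/intensity triplets
make_pl <- function(residues, shift_n, shift_h, intensity,
                    atom_group = "bb", label = "fixture") {
  suppressWarnings(peak_list(data.frame(
    residue_id = residues,
    atom_group = rep_len(atom_group, length(residues)),
    shift_n = shift_n, shift_h = shift_h, intensity = intensity,
    stringsAsFactors = FALSE), label = label))
}

# a randomly populated but reproducible peak list
random_pl <- function(n, seed = 1, label = "random") {
  set.seed(seed)
  make_pl(seq_len(n),
          shift_n = runif(n, 105, 130),
          shift_h = runif(n, 6.5, 10),
          intensity = runif(n, 1e5, 1e7),
          label = label)
}

write_sparky_fixture <- function(lines) {
  path <- tempfile(fileext = ".list")
  writeLines(lines, path)
  path
}

# independent RK4 integrator of dA/dt = -k1 A, dB/dt = k1 A - k2 B
# (oracle for the closed-form consecutive model)
ode_consecutive <- function(t_end, k1, k2, dt = 1e-4) {
  a <- 1; b <- 0
  f <- function(s) c(-k1 * s[1], k1 * s[1] - k2 * s[2])
  t <- 0
  s <- c(a, b)
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1v <- f(s)
    k2v <- f(s + h / 2 * k1v)
    k3v <- f(s + h / 2 * k2v)
    k4v <- f(s + h * k3v)
    s <- s + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    t <- t + h
  }
  c(f_a = s[1], f_b = s[2], f_c = 1 - s[1] - s[2])
}
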