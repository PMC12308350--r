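# reference parameter set used throughout: trastuzumab-like rates on an
# SK-OV3-like cell (kon 1e5 /s/M, koff 1e-4 /s, D 1e-14 m^2/s, 1e4 antigens)
reference_params <- function(Ainit = 1e-10, rtot = 1e4, ...) {
  model_params(kon = 1e5, koff = 1e-4, D = 1e-14, rtot = rtot,
               Ainit = Ainit, ...)
}

# log-uniform draws over the literature ranges (plus dose 1e-12..1e-5 M)
random_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    model_params(kon = 10^runif(1, 4, 6),
                 koff = 10^runif(1, -6, -3),
                 D = 10^runif(1, -15, -13),
                 rtot = 10^runif(1, 4, 6),
                 Ainit = 10^runif(1, -12, -5))
  })
}

rel_diff <- function(a, b, floor = 1) abs(a - b) / pmax(abs(b), floor)
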