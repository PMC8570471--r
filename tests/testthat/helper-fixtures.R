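# Shared fixtures: small substrates and uniform phantoms used across the
# test files.

stick_substrate <- function(ad = 2, orientation = "coherent", kappa = 2)
  substrate(compartment(1, ad, 0, orientation = orientation,
                        mu = c(0, 0, 1), kappa = kappa))

two_iso_substrate <- function(d1 = 1, d2 = 2)
  substrate(list(compartment(0.5, d1, d1), compartment(0.5, d2, d2)))

iso_substrate <- function(d = 0.7)
  substrate(compartment(1, d, d))

# phantom with the same substrate in every region (including the border)
uniform_layout <- function(s, nx = 8, ny = 8, nz = 1) {
  subs <- list(CC = s, IC = s, HC = s, CX = s, TH = s, CSF = s)
  phantom_layout(nx, ny, nz, substrates = subs)
}

# muA-style protocol at reduced b-values (cumulant regime)
small_b_mua_protocol <- function(bvals = c(0.4, 0.2), n_dir = c(30L, 30L),
                                 seed = 3)
  build_protocol("mua", config = list(bvals = bvals, n_dir = n_dir,
                                      n_b0 = 8L), seed = seed)

# single-compartment coherent-tensor layout: voxel signal is exactly
# monoexponential in b, so log-linear fits are exact
gaussian_layout <- function(ad = 1.0, rd = 0.5, lambda_c = 0.006,
                            nx = 8, ny = 8, nz = 1) {
  s <- substrate(compartment(1, ad, rd, orientation = "coherent",
                             mu = c(1, 0, 0), lambda_c = lambda_c))
  uniform_layout(s, nx, ny, nz)
}
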