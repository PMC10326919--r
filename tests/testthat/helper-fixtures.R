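# Shared fixture builders. All synthetic data is generated in code under
# fixed seeds; no binary fixtures.

# A nominal spectrum straight from a named channel vector.
make_nominal <- function(channels, id, truth = "known_positive",
                         compound = "fixture", source = "lab1") {
  nominal_spectrum(channels,
                   meta = list(spectrum_id = id, compound = compound,
                               truth = truth, source = source))
}

# An abundance matrix built directly from numeric columns (bypassing spectra)
# for regression-fitting tests with known generating coefficients.
make_matrix <- function(values, ids = NULL, truth = "known_positive") {
  ids <- ids %||% sprintf("s%03d", seq_len(nrow(values)))
  rownames(values) <- ids
  structure(values, truth = stats::setNames(rep(truth, nrow(values)), ids),
            class = c("abundance_matrix", class(values)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default-conditions training matrix from the synthetic generator.
training_matrix <- function(n = 128, seed = 1, k = 20, noise_sd = 0.5) {
  spec <- cocaine_like_spec(noise_sd = noise_sd)
  tr <- as_nominal(simulate_replicates(spec, n, seed = seed))
  panel <- select_top_k(tr, k)
  assemble_matrix(tr, panel)
}

# Run the installed CLI in a working directory; returns exit status.
run_cli <- function(args, wd) {
  cli <- system.file("cli", "easi.R", package = "easispec")
  stopifnot(nzchar(cli))
  withr::with_dir(wd, {
    system2("Rscript", c(cli, args), stdout = FALSE, stderr = FALSE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  })
}
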