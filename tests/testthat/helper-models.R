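## Shared fixtures: built once per test run, cached lazily.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

toy_net <- function() fixture("toy_net", function() build_toy_core())
toy_net_irrev <- function() fixture("toy_net_irrev", function()
  build_toy_core(icdh_reversible = FALSE))
ref_env <- function() fixture("ref_env", function() diel_environment())
ref_cs <- function() fixture("ref_cs", function() diel_constraints())

diel_variant <- function(mode, net = toy_net()) {
  key <- paste0("model_", mode, "_", substr(digest_ids(net), 1, 6))
  fixture(key, function() {
    cs <- ref_cs()
    capacity <- switch(mode,
                       c3 = cs$vacuole_capacity_c3,
                       cam = cs$vacuole_capacity_c3 * cs$cam_capacity_factor,
                       unlimited = Inf)
    couple_water_loss(apply_vacuole_capacity(
      expand_diel(net, ref_env(), cs), capacity))
  })
}

digest_ids <- function(net) paste0(nrow(net$reactions), "_",
                                   sum(net$reactions$lb < 0))

## reference maximum phloem output of the C3-anatomy model
ref_pstar <- function() fixture("ref_pstar", function()
  maximize_phloem(diel_variant("c3"), minimize_flux_after = FALSE)$phloem_output)

## water-minimal solutions at 80% of the C3 maximum
sol80 <- function(mode, net = toy_net()) {
  key <- paste0("sol80_", mode, "_", substr(digest_ids(net), 1, 6))
  fixture(key, function()
    minimize_water(diel_variant(mode, net), 0.8 * ref_pstar()))
}

## steady-state residual of a solution on the balance rows of its model
balance_residual <- function(sol) {
  model <- sol$model
  x <- c(as.numeric(sol$fluxes), as.numeric(sol$linkers))
  nbal <- sum(model$row_kind == "balance")
  nv <- length(x)
  A <- Matrix::sparseMatrix(i = model$tri$i, j = model$tri$j, x = model$tri$x,
                            dims = c(length(model$rhs),
                                     nrow(model$vars)))
  Abal <- A[model$row_kind == "balance", seq_len(nv), drop = FALSE]
  max(abs(as.numeric(Abal %*% x)))
}

## variable columns of a tagged reaction across all steps
rxn_cols_test <- function(model, tag) {
  which(model$vars$kind == "rxn" & model$vars$id == model$tags[[tag]])
}
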