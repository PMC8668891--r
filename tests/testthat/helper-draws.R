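# Hand-built parameter draws for controlled simulation scenarios.

# single panmictic population: both splits at the present, all sizes N
single_pop_draw <- function(N) {
  d <- list(N_P1 = N, N_P2 = N, N_P3 = N, N_anc12 = N, N_anc123 = N,
            N_found_P1 = N, N_found_P2 = N, N_found_P3 = N,
            T_change_P1 = 0, T_change_P2 = 0, T_change_P3 = 0,
            T_split12 = 0, T_split123 = 0, T_trans12 = 0,
            M12 = 0, M13 = 0, M23 = 0,
            shape1_Ne = NA_real_, shape2_Ne = NA_real_,
            shape1_M = NA_real_, shape2_M = NA_real_,
            category = "AM.SI", submodel = "NeHom.MHom")
  class(d) <- "param_draw"
  d
}

# three isolated populations of size N with given split times, no migration
isolation_draw <- function(N, t12, t123) {
  d <- single_pop_draw(N)
  d$T_split12 <- t12
  d$T_split123 <- t123
  d$T_trans12 <- t12   # AM interval [t12, t12] is empty: fully isolated
  d
}

# secondary-contact draw with permanent P1-P2 migration at rate m12
contact_draw <- function(N, t12, t123, m12, m13 = 0, m23 = 0,
                         category = "SC.SI") {
  d <- single_pop_draw(N)
  d$T_split12 <- t12
  d$T_split123 <- t123
  d$T_trans12 <- t12
  d$M12 <- m12
  d$M13 <- m13
  d$M23 <- m23
  d$category <- category
  d
}

tiny_specs <- function(n, L = 500) data.frame(length = rep(L, n))
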