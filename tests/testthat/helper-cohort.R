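# Shared synthetic fixtures, built once per test run. Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_surface <- function() fixture("tiny_surface", function() {
  generate_surface(600, 40, seed = 11)
})

tiny_truth <- function() fixture("tiny_truth", function() {
  plant_group_networks(tiny_surface(), k_true = 6, r_w = 0.4, r_b = 0.05,
                       seed = 11)
})

# 8 subjects, individual deviations concentrated at borders; used by
# reliability / consensus / metrics properties.
small_cohort <- function() fixture("small_cohort", function() {
  simulate_cohort(n_subjects = 8, sessions_per_subject = 1,
                  n_vertices = 600, n_parcels = 40, k_true = 6,
                  flip_rate = 0.12, boundary_bias = 4, n_frames = 300,
                  noise_sd = 0.5, p_high = 0.05, seed = 21)
})

# per-session quantities derived from the small cohort, computed lazily
cohort_vfc <- function() fixture("cohort_vfc", function() {
  ch <- small_cohort()
  lapply(ch$sessions, vertex_parcel_fc, surface = ch$surface)
})

cohort_assignments <- function() fixture("cohort_assignments", function() {
  ch <- small_cohort()
  lapply(cohort_vfc(), match_templates, template_set = ch$truth$templates)
})

expect_fraction <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", x, tol, target))
}
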