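# shared fixtures, all generated in code

# random symbolic string of given length/alphabet
random_string <- function(len, alphabet) {
  symbolic_string(sample.int(alphabet, len, replace = TRUE), alphabet)
}

# synthetic tidy surface table: per-subject entropies drawn around a
# group-specific mean, same (tau, n) grid for everyone
make_surface_tbl <- function(group_means, n_subjects = 8, taus = 1:3,
                             ns = c(2, 4, 8), sd = 1) {
  grid <- expand.grid(tau = taus, n = ns)
  purrr::imap_dfr(group_means, function(mu, g) {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      tibble::tibble(
        subject_id = sprintf("%s%02d", g, i), group = g,
        tau = grid$tau, n = grid$n,
        entropy = pmax(0, stats::rnorm(nrow(grid), mean = mu, sd = sd)),
        length = 1000L, out_of_range = 0L)
    })
  })
}

# duplicate a surface table under a new group label (exchangeable copy)
copy_surfaces_as <- function(surfaces, new_group) {
  dplyr::mutate(surfaces, group = new_group,
                subject_id = paste0(subject_id, "_copy"))
}
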