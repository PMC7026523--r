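# Shared fixtures, built lazily once per session and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# constant-height disk in a field; returns height map + label matrix
make_disk_field <- function(n = 128, r = 20, h = 3000, center = NULL) {
  center <- center %||% c((n + 1) / 2, (n + 1) / 2)
  dx <- matrix(rep(seq_len(n) - center[1], n), n)
  dy <- t(matrix(rep(seq_len(n) - center[2], n), n))
  mask <- dx^2 + dy^2 <= r^2
  list(height = ifelse(mask, h, 0), labels = ifelse(mask, 1L, 0L) * 1L)
}

# constant-height axis-aligned filled ellipse
make_ellipse_field <- function(n = 192, a = 40, b = 20, h = 2000) {
  c0 <- (n + 1) / 2
  dx <- matrix(rep(seq_len(n) - c0, n), n)
  dy <- t(dx)
  mask <- (dx / a)^2 + (dy / b)^2 <= 1
  list(height = ifelse(mask, h, 0), labels = ifelse(mask, 1L, 0L) * 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small archetype dataset (feature table) used across classifier tests
small_archetypes <- function() memo("small_archetypes", function() {
  lp <- list(line_profile("E_arch", 70, blend_m = 0),
             line_profile("M_arch", 70, blend_m = 1))
  simulate_feature_table(sim_config(lp, field_size = 1024,
                                    cells_per_field = 12, seed = 420))
})

# default-population feature table (the full 1295-cell study conditions)
default_table <- function() memo("default_table", function() {
  simulate_feature_table(sim_config(seed = 2024))
})

# blend-sweep population for transfer-score validity checks
sweep_table <- function() memo("sweep_table", function() {
  lp <- list(line_profile("SWEEP", 500, blend_beta = c(1, 1)))
  simulate_feature_table(sim_config(lp, field_size = 1024,
                                    cells_per_field = 12, seed = 77))
})

# EM model trained on a partition of the default archetype lines
default_model <- function() memo("default_model", function() {
  tab <- default_table()
  arch <- tab[tab$line %in% c("GIE", "HGF"), ]
  part <- partition_data(arch, test_n = 80, seed = 2024)
  model <- suppressWarnings(em_train(part$train, k = 6, seed = 2024))
  list(part = part, model = model)
})
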