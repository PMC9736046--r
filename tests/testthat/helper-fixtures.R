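# Shared fixtures: tiny geometries, a smoke-scale network configuration and
# a session-cached synthetic dataset so expensive setup runs once.

# Make the package's internal autodiff operators visible to the oracle tests.
local({
  ns <- asNamespace("vesselseg")
  for (nm in ls(ns, pattern = "^(ag_|im2col|unet_|conv_fwd|bundle_values|downsample_mean|with_preserved_seed|rot90k)")) {
    assign(nm, get(nm, envir = ns), envir = parent.env(environment()))
  }
})

smoke_geometry <- function() patch_geometry(48L, 96L)

smoke_config <- function(...) {
  mfnet_config(geometry = smoke_geometry(),
               main_channels = c(8L, 16L, 32L),
               pre_channels = c(8L, 16L, 32L),
               context_channels = c(4L, 8L, 16L),
               fuse_channels = 8L, fuse_out = 8L, corr_channels = 4L,
               edge_channels = 4L, aca_r = 4L, gsa_M = 6L, gsa_heads = 1L,
               ...)
}

.fixture_cache <- new.env(parent = emptyenv())

# 12 train + 4 test synthetic records at 192x192, preprocessed, cached.
fixture_suite <- function() {
  if (is.null(.fixture_cache$suite)) {
    dir <- file.path(tempdir(), "vesselseg-fixture")
    if (!dir.exists(file.path(dir, "images"))) {
      make_fixture_suite(dir, n_train = 12L, n_test = 4L, seed = 1L)
    }
    lt <- discover_dataset(dir, "images/train*.png")
    le <- discover_dataset(dir, "images/test*.png")
    .fixture_cache$suite <- list(
      train = lapply(load_dataset(lt), preprocess_record),
      test = lapply(load_dataset(le), preprocess_record),
      dir = dir
    )
  }
  .fixture_cache$suite
}

# One small preprocessed synthetic record (96x96) for fast geometry tests.
tiny_record <- function(seed = 5L) {
  key <- paste0("rec", seed)
  if (is.null(.fixture_cache[[key]])) {
    rec <- generate_fundus(vessel_spec(image_size = c(96L, 96L), n_trees = 3L,
                                       seed = seed))
    .fixture_cache[[key]] <- preprocess_record(rec)
  }
  .fixture_cache[[key]]
}

# Naive reference softmax used by several oracles.
ref_softmax_rows <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}
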