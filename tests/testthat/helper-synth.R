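# Shared fixtures: all synthetic data is generated in code at test time.

# A small image spec used across tests; counts overridable.
tiny_spec <- function(counts = c(MA = 0, EX = 0, HEM = 0), seed = 1L,
                      size = 96L) {
  synth_spec(size, size, lesion_counts = counts,
             blob_radius_range = list(MA = c(2, 4), EX = c(4, 7),
                                      HEM = c(6, 9)),
             seed = seed)
}

# The scaled-down segmentation protocol used by the training tests:
# base_filters 8, batch 32, 3 epochs, 5 folds, dense tiling of 96 px
# images with 32 px patches.
tiny_seg_config <- function(class, seed = 202L, ...) {
  seg_config(n = 32, base_filters = 8, batch_size = 32, epochs = 3,
             k_folds = 5, patch_stride = 8, seed = seed,
             lesion_class = class, ...)
}

# Independent connected-component oracle (EBImage), used to check the
# edge/contour counting path.
cc_oracle <- function(mask) max(EBImage::bwlabel(mask))

# Deterministic synthetic dataset in a session temp dir.
make_dataset <- function(n_healthy, n_dr, seed, dir = tempfile("ds")) {
  generate_fundus_dataset(n_healthy, n_dr, tiny_spec(c(MA = 4, EX = 3,
                                                       HEM = 2)),
                          dir, seed = seed)
}
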