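## Independent brute-force oracles and shared tiny fixtures.

## all integer partitions of n, built as non-decreasing part sequences
## (independent of the package's descending-lexicographic recursion)
oracle_partitions <- function(n) {
  grow <- function(remaining, min_part) {
    if (remaining == 0) return(list(integer(0)))
    if (min_part > remaining) return(list())
    out <- list()
    for (p in min_part:remaining)
      for (rest in grow(remaining - p, p))
        out[[length(out) + 1L]] <- c(p, rest)
    out
  }
  lapply(grow(n, 1L), function(p) sort(p, decreasing = TRUE))
}

## all non-empty subsets of 1..l via binary masks
oracle_subsets <- function(l) {
  out <- list()
  for (mask in seq_len(2^l - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(l)]
    out[[length(out) + 1L]] <- which(bits == 1L)
  }
  out
}

canon_partition_set <- function(parts) {
  sort(vapply(parts, function(p) paste(p, collapse = "."), character(1)))
}

## a small, quickly evaluated denoiser used in structural tests
tiny_model <- function(T = 40L, layers = 2L, ds = 16L, dv = 4L, seed = 7L) {
  gvp_denoiser(layers = layers, ds = ds, dv = dv,
               schedule = make_schedule(T), seed = seed)
}

## octahedral fixture with six monodentate ligands
hexa_mono <- function(seed = 1L, metal = "Fe") {
  make_toy_complex(metal, c("aqua", "ammine", "chloro", "cyano",
                            "carbonyl", "pyridyl"),
                   geometry = "octahedral", seed = seed,
                   source_id = sprintf("hexa_mono_%d", seed))
}

## octahedral fixture with two tridentate ligands
bis_tri <- function(seed = 2L, metal = "Fe") {
  make_toy_complex(metal, c("dien", "trieth"), geometry = "octahedral",
                   seed = seed, source_id = sprintf("bis_tri_%d", seed))
}

max_abs <- function(x) max(abs(x))

## rotate every 3D vector channel of a (3N) x dv feature matrix
rotate_vchannels <- function(Vm, R) {
  out <- Vm
  for (c_ in seq_len(ncol(Vm))) {
    M <- matrix(Vm[, c_], ncol = 3, byrow = TRUE)
    out[, c_] <- as.vector(t(M %*% t(R)))
  }
  out
}
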