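# Small constructors used across tests.

makeVolume <- function(values, spacing = c(1, 1, 1)) {
  new("CtVolume", values = values, spacing = spacing, orientation = NULL)
}

makeMask <- function(values, spacing = c(1, 1, 1)) {
  new("RoiMask", values = values, spacing = spacing)
}

# VoxelSample directly from a numeric vector (positions on a line)
makeSample <- function(hu, voxelVolume = 1) {
  n <- length(hu)
  new("VoxelSample", hu = as.double(hu),
      positions = cbind(x = seq_len(n), y = rep(1L, n), z = rep(1L, n)),
      dims = c(n, 1L, 1L), voxelVolume = voxelVolume)
}

# VoxelSample wrapping a full 3-D grid of HU values (all voxels foreground)
gridSample <- function(arr, spacing = c(1, 1, 1)) {
  extractRoiVoxels(makeVolume(arr, spacing),
                   makeMask(array(TRUE, dim(arr)), spacing))
}

# QuantizedRoi directly from an integer level grid (0 = background)
makeQuantized <- function(levels, nLevels = max(levels)) {
  new("QuantizedRoi", levels = levels, nLevels = as.integer(nLevels),
      huRange = c(0, 1))
}

# the worked 4x4x1 grid: rows [1 1 2 2 / 1 1 2 2 / 3 3 3 3 / 1 1 1 1]
workedGrid <- function() {
  g <- array(0L, c(4, 4, 1))
  g[, , 1] <- matrix(c(1, 1, 2, 2,
                       1, 1, 2, 2,
                       3, 3, 3, 3,
                       1, 1, 1, 1), nrow = 4, byrow = TRUE)
  g
}
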