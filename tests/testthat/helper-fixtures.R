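# Shared small-scale fixtures. Tests run the same physics at reduced grid
# sizes; the full-scale defaults are exercised by the acceptance tests.

# tiny grid/geometry pair for operator-level tests
tinyGrid <- function(n = 8L) VoxelGrid(n, n, 1L, 3, 3, 3)
tinyGeom <- function(nAngles = 8L, n = 8L)
  ProjectionGeometry(nAngles = nAngles, grid = tinyGrid(n))

# reduced-scale phantom: same 4:1 hot-sphere structure on a 64-voxel grid
smallPhantomSpec <- function()
  NemaPhantomSpec(bodySemiAxes = c(95, 85),
                  sphereCenters = cbind(c(40, 0, -40, 0), c(0, 40, 0, -40)))

smallPhantomGrid <- function() VoxelGrid(64L, 64L, 1L, 3.12, 3.12, 2.68)
smallPhantomGeom <- function() ProjectionGeometry(nAngles = 40L,
                                                  grid = smallPhantomGrid())
smallPhantomLayout <- function(grid = smallPhantomGrid())
  layoutRois(smallPhantomSpec(), grid, ringRadius = 68, clearanceMm = 5)

# reduced-scale patient: coarser voxels, thinner slab, liver large enough for
# the 3-cm VOI
smallPatientGrid <- function() VoxelGrid(96L, 96L, 10L, 4, 4, 5)
smallPatientSpec <- function(lesions = list(LesionSpec(c(-60, -20, 0), 14, 10)))
  PatientSpec(bodySemiAxes = c(140, 95), liverCenter = c(50, 10, 0),
              liverSemiAxes = c(55, 42, 22), lesions = lesions)
smallPatientGeom <- function() ProjectionGeometry(nAngles = 40L,
                                                  grid = smallPatientGrid())

# brute-force dense projector built voxel-by-voxel through project(): an
# independent materialization used as the adjointness oracle
explicitSystemMatrix <- function(grid, geom) {
  nxy <- grid@nx * grid@ny
  cols <- vapply(seq_len(nxy), function(j) {
    e <- array(0, c(grid@nx, grid@ny, 1L))
    e[j] <- 1
    as.numeric(sinoData(project(ActivityVolume(e, grid), geom)))
  }, numeric(geom@nBins * geom@nAngles))
  cols
}
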