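# MRC, particle and OBJ interchange.

test_that("MRC round trip preserves float32 data bitwise and the voxel size", {
  v <- volume3d(array(rnorm(4 * 4 * 4), c(4, 4, 4)), voxel_size = 17.4)
  p1 <- file.path(tempdir(), "rt1.mrc")
  p2 <- file.path(tempdir(), "rt2.mrc")
  write_mrc(v, p1)
  v1 <- read_mrc(p1)
  expect_equal(v1$voxel_size, 17.4, tolerance = 1e-6)
  expect_equal(dim(v1$data), c(4, 4, 4))
  # doubles are quantized to float32 on first write; thereafter lossless
  expect_lt(max(abs(v1$data - v$data)), 1e-6)
  write_mrc(v1, p2)
  v2 <- read_mrc(p2)
  expect_identical(v2$data, v1$data)
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   {
                     p3 <- file.path(tempdir(), "rt3.mrc")
                     write_mrc(v2, p3)
                     readBin(p3, "raw", file.size(p3))
                   })
})

test_that("read_mrc reads a file produced by an independent MRC writer", {
  # header written field by field from the MRC2014 specification, not via
  # the package's writer
  path <- file.path(tempdir(), "indep.mrc")
  con <- file(path, "wb")
  dat <- as.numeric(1:24) / 10
  dims <- c(2L, 3L, 4L)
  writeBin(dims, con, size = 4, endian = "little")              # nx ny nz
  writeBin(2L, con, size = 4, endian = "little")                # mode 2
  writeBin(c(0L, 0L, 0L), con, size = 4, endian = "little")     # nstart
  writeBin(dims, con, size = 4, endian = "little")              # mx my mz
  writeBin(dims * 17.4, con, size = 4, endian = "little")       # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")     # cellb
  writeBin(1:3, con, size = 4, endian = "little")               # mapc/r/s
  writeBin(range(dat), con, size = 4, endian = "little")        # dmin dmax
  writeBin(mean(dat), con, size = 4, endian = "little")         # dmean
  writeBin(c(1L, 0L), con, size = 4, endian = "little")         # ispg nsymbt
  writeBin(integer(25), con, size = 4, endian = "little")       # extra
  writeBin(c(0, 0, 0), con, size = 4, endian = "little")        # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)              # stamp
  writeBin(stats::sd(dat), con, size = 4, endian = "little")    # rms
  writeBin(0L, con, size = 4, endian = "little")                # nlabl
  writeBin(raw(800), con)
  writeBin(dat, con, size = 4, endian = "little")
  close(con)
  v <- read_mrc(path)
  expect_equal(v$voxel_size, 17.4, tolerance = 1e-5)
  expect_equal(dim(v$data), c(2, 3, 4))
  expect_equal(as.vector(v$data), dat, tolerance = 1e-6)
})

test_that("integer MRC modes are read and cast to double", {
  path <- file.path(tempdir(), "mode1.mrc")
  # reuse the package writer's header but patch mode and payload by hand
  v <- volume3d(array(0, c(2, 2, 2)), voxel_size = 10)
  write_mrc(v, path)
  raw <- readBin(path, "raw", file.size(path))
  raw[13:16] <- writeBin(1L, raw(), size = 4, endian = "little") # mode 1
  payload <- writeBin(as.integer(c(-3, -2, -1, 0, 1, 2, 3, 4)), raw(),
                      size = 2, endian = "little")
  writeBin(c(raw[1:1024], payload), path)
  v1 <- read_mrc(path)
  expect_equal(as.vector(v1$data), c(-3, -2, -1, 0, 1, 2, 3, 4))
})

test_that("malformed MRC inputs give informative errors", {
  bad <- file.path(tempdir(), "trunc.mrc")
  v <- volume3d(array(rnorm(64), c(4, 4, 4)))
  write_mrc(v, bad)
  raw <- readBin(bad, "raw", file.size(bad))
  writeBin(raw[1:(length(raw) - 50)], bad)
  expect_error(read_mrc(bad), "truncated")

  mode_bad <- file.path(tempdir(), "mode.mrc")
  write_mrc(v, mode_bad)
  raw <- readBin(mode_bad, "raw", file.size(mode_bad))
  raw[13:16] <- writeBin(5L, raw(), size = 4, endian = "little")
  writeBin(raw, mode_bad)
  expect_error(read_mrc(mode_bad), "mode 5")

  expect_error(read_mrc(file.path(tempdir(), "nope.mrc")), "exist")
})

test_that("anisotropic voxel sizes warn and fall back to the x spacing", {
  path <- file.path(tempdir(), "aniso.mrc")
  v <- volume3d(array(0, c(2, 2, 2)), voxel_size = 10)
  write_mrc(v, path)
  raw <- readBin(path, "raw", file.size(path))
  # cella y word (word 12) -> 2 * 12.0
  raw[45:48] <- writeBin(24, raw(), size = 4, endian = "little")
  writeBin(raw, path)
  expect_warning(v2 <- read_mrc(path), "anisotropic")
  expect_equal(v2$voxel_size, 10, tolerance = 1e-6)
})

test_that("particle files serialize exactly as specified", {
  ps <- particle_set(11, 3, 8)
  p <- file.path(tempdir(), "one.txt")
  write_particles(ps, p, "tsv")
  expect_identical(readLines(p), "11\t3\t8")

  ps3 <- particle_set(c(1, 2), c(3, 4), c(5, 6), weight = c(2, 1))
  write_particles(ps3, p, "tsv")
  lines <- readLines(p)
  expect_length(lines, 2)
  toks <- unlist(strsplit(lines, "\t"))
  expect_true(all(grepl("^-?[0-9]+$", toks))) # integer tokens only

  empty <- particle_set()
  ps_star <- file.path(tempdir(), "empty.star")
  write_particles(empty, ps_star, "star")
  got <- readLines(ps_star)
  expect_true(any(got == "loop_"))
  expect_true(any(grepl("_rlnCoordinateX", got)))
  expect_false(any(grepl("^[0-9]", got))) # zero data rows

  write_particles(ps3, ps_star, "star")
  back <- read_particles(ps_star, "star")
  expect_equal(back$x, ps3$x)
  expect_equal(back$z, ps3$z)

  write_particles(ps3, p, "tsv", one_based = TRUE)
  back1 <- read_particles(p, "tsv")
  expect_equal(back1$x, ps3$x + 1L)
})

test_that("particle sets validate bounds, weights and integrality", {
  expect_error(particle_set(5, 5, 5, bounds = c(4, 8, 8)), "bounds")
  expect_error(particle_set(1, 1, 1, weight = -1), "non-negative")
  expect_error(particle_set(1.5, 1, 1), "integers")
  expect_silent(particle_set(3, 3, 3, bounds = c(4, 4, 4)))
})

test_that("OBJ writing is 1-based, validated, and round-trips topology", {
  m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3)))
  p <- file.path(tempdir(), "tri.obj")
  write_mesh_obj(m, p)
  lines <- readLines(p)
  expect_identical(sum(startsWith(lines, "v ")), 3L)
  expect_identical(lines[4], "f 1 2 3")

  expect_error(tri_mesh(m$vertices, rbind(c(1, 2, 4))), "existing")

  sph <- volume_to_mesh(volume3d(sphere_field(c(24, 24, 24),
                                              c(11.5, 11.5, 11.5), 7),
                                 voxel_size = 1), 0.5)
  write_mesh_obj(sph, p)
  indep <- oracle_parse_obj(p)
  expect_identical(nrow(indep$vertices), nrow(sph$vertices))
  expect_identical(nrow(indep$faces), nrow(sph$faces))
  expect_identical(max(indep$faces), nrow(sph$vertices)) # fully used, 1-based
  back <- read_mesh_obj(p)
  expect_equal(back$faces, sph$faces, ignore_attr = TRUE)

  emptym <- tri_mesh()
  write_mesh_obj(emptym, p)
  expect_identical(length(readLines(p)), 0L)
})
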