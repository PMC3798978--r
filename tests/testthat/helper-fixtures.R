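# shared fixtures, built once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.cache[[name]])) .cache[[name]] <- builder()
  .cache[[name]]
}

circle_curve <- function(n = 64, r = 10) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  closed_curve(cbind(r * cos(th), r * sin(th), 0))
}

trefoil_curve <- function(n = 140) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  closed_curve(cbind(sin(t) + 2 * sin(2 * t), cos(t) - 2 * cos(2 * t), -sin(3 * t)))
}

figure8_curve <- function(n = 200) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  closed_curve(cbind((2 + cos(2 * t)) * cos(3 * t), (2 + cos(2 * t)) * sin(3 * t),
                     sin(4 * t)))
}

default_substrate <- function() cached("substrate", function() substrate_geometry())

assembly_state <- function(state) {
  cached(paste0("assembly_", state), function() {
    comp <- make_toy_components(fixture_spec(), state)
    assemble_invertasome(assembly_config(comp))
  })
}

rotation_products <- function(nmax = 4) {
  cached(paste0("products_", nmax), function() {
    s <- default_substrate()
    lapply(0:nmax, function(n) simulate_rotation(s, n))
  })
}

mirror_assembly <- function(a) {
  flip <- function(xyz) { xyz[, 1] <- -xyz[, 1]; xyz }
  a$fis1$xyz <- flip(a$fis1$xyz); a$fis2$xyz <- flip(a$fis2$xyz)
  for (hs in names(a$hin)) a$hin[[hs]]$xyz <- flip(a$hin[[hs]]$xyz)
  for (dp in c("enhancer", "hix1", "hix2")) {
    a[[dp]]$backbone <- lapply(a[[dp]]$backbone, flip)
    a[[dp]]$frames <- lapply(a[[dp]]$frames, function(f) {
      f$origin[1] <- -f$origin[1]; f$axes[1, ] <- -f$axes[1, ]; f
    })
  }
  a
}
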