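# Independent oracles used across the suite.

WALL <- blockcpm::cpm_wall_id()

# Side-counting surface by explicit face enumeration (independent of the
# package's C++ counter).
oracle_side_surface <- function(field, id) {
  dm <- dim(field)
  faces <- 0L
  for (x in seq_len(dm[1])) for (y in seq_len(dm[2])) for (z in seq_len(dm[3])) {
    if (field[x, y, z] != id) next
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(x, y, z) + d
      if (any(p < 1) || any(p > dm)) next       # implicit wall: not counted
      w <- field[p[1], p[2], p[3]]
      if (w != id && w != WALL) faces <- faces + 1L
    }
  }
  faces
}

# Total Hamiltonian of a committed state by full recomputation.
# cells: data.frame(id, type, v0, s0); types: cell_types() table.
oracle_energy <- function(field, cells, types, metric = "side") {
  E <- 0
  for (q in seq_len(nrow(cells))) {
    ti <- match(cells$type[q], types$name)
    if (types$is_liquid[ti] || types$is_solid[ti]) next
    v <- sum(field == cells$id[q])
    s <- blockcpm::marching_surface(field, cells$id[q])
    if (metric == "side") s <- blockcpm::side_count_surface(field, cells$id[q])
    E <- E + types$lambda_V[ti] * (v - cells$v0[q])^2 +
      types$lambda_S[ti] * (s - cells$s0[q])^2
  }
  sh <- blockcpm::shared_surfaces(field)
  if (nrow(sh)) {
    idtype <- stats::setNames(match(cells$type, types$name), cells$id)
    for (k in seq_len(nrow(sh))) {
      E <- E + types$adhesion[idtype[as.character(sh$i[k])],
                              idtype[as.character(sh$j[k])]] * sh$surface[k]
    }
  }
  E
}

# A random small multi-cell state plus its committed cell table.
random_state <- function(dim = c(5, 5, 5), n_cells = 3, seed = 1) {
  set.seed(seed)
  field <- array(sample(0:n_cells, prod(dim), replace = TRUE), dim = dim)
  types <- blockcpm::cell_types(list(
    liquid = list(liquid = TRUE),
    a = list(V0 = 20, S0 = 60, lambda_V = 1, lambda_S = 0.5,
             adhesion = list(liquid = 2, a = 4))))
  cells <- data.frame(id = 0:n_cells,
                      type = c("liquid", rep("a", n_cells)),
                      v0 = c(0, rep(20, n_cells)),
                      s0 = c(0, rep(60, n_cells)))
  cells$v <- vapply(cells$id, function(id) sum(field == id), numeric(1))
  cells$s_side <- vapply(cells$id, function(id)
    blockcpm::side_count_surface(field, id), numeric(1))
  cells$s_march <- vapply(cells$id, function(id)
    blockcpm::marching_surface(field, id), numeric(1))
  list(field = field, cells = cells, types = types)
}

# Minimal working configuration for engine tests.
tiny_config <- function(...) {
  over <- list(...)
  base <- list(
    domain = list(size = c(16, 8, 8), blocks = c(2, 1, 1), colors = 8,
                  stencil = 27, metric = "marching", mean_step = 2,
                  temperature = 4, seed = 5),
    celltypes = list(
      liquid = list(liquid = TRUE),
      cell = list(V0 = 64, S0 = 100, lambda_V = 1, lambda_S = 0.5,
                  adhesion = list(liquid = 0, cell = 0))),
    init = list(list(shape = "cube", corner = c(6, 2, 2), size = 4, type = "cell")))
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  blockcpm::cpm_config(base)
}
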