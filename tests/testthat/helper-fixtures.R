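# fixture builders shared by the suite; everything is generated in code

# tiny plate: one strain per 2x2 block, sizes given per strain
toy_plate <- function(sizes, plate_id = "P1", n_rows = 4, n_cols = 4,
                      condition = NULL) {
  nb <- (n_rows / 2) * (n_cols / 2)
  stopifnot(length(sizes) <= nb)
  br <- rep(seq_len(n_rows / 2), each = n_cols / 2)[seq_along(sizes)]
  bc <- rep(seq_len(n_cols / 2), times = n_rows / 2)[seq_along(sizes)]
  wells <- data.frame(
    row = c(2 * br - 1, 2 * br - 1, 2 * br, 2 * br),
    col = c(2 * bc - 1, 2 * bc, 2 * bc - 1, 2 * bc),
    strain_id = rep(names(sizes), 4),
    colony_size = rep(unname(sizes), 4),
    is_border = FALSE)
  plate_grid(plate_id, condition, n_rows, n_cols, wells)
}

# growth-curve set from target fitness levels: constant-OD curves make the
# AUC (and so fitness) exact by construction
const_curves <- function(map, levels, t_end = 24, dt = 0.25) {
  times <- seq(0, t_end, by = dt)
  od <- matrix(rep(levels, each = length(times)), nrow = length(levels),
               byrow = TRUE)
  growth_curves(times, od, map)
}

# independent step-up FDR oracle, straight from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[o[i]] <- min(1, min(n * p[o[i:n]] / seq(i, n)))
  }
  adj
}

# brute-force overlap counts by membership enumeration
overlap_oracle <- function(sets) {
  univ <- unique(unlist(sets))
  memb <- sapply(sets, function(s) univ %in% s)
  if (!is.matrix(memb)) memb <- matrix(memb, nrow = length(univ))
  list(full = sum(rowSums(memb) == length(sets)),
       union = sum(rowSums(memb) > 0))
}
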