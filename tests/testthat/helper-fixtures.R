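# Shared fixture builders. Everything is generated in code; the small
# simulated study is cached per test run since several files use it.

make_fixes <- function(x, y, elev = 200, t = seq_along(x), group = "A",
                       follow_id = "f1") {
  tibble::tibble(time = t, x = x, y = y, elev = elev, group = group,
                 follow_id = follow_id)
}

# straight-line track at a given speed (m/min), 1 fix per minute
make_track <- function(from, to, speed = 50, t0 = 0, elev = 200,
                       group = "A", follow_id = "f1") {
  d <- sqrt(sum((to - from)^2))
  n <- max(2, ceiling(d / speed) + 1)
  f <- seq(0, 1, length.out = n)
  tibble::tibble(time = t0 + seq_len(n) - 1,
                 x = from[1] + f * (to[1] - from[1]),
                 y = from[2] + f * (to[2] - from[2]),
                 elev = elev, group = group, follow_id = follow_id)
}

.sim_cache <- new.env(parent = emptyenv())

# one small study shared across test files (10 days keeps extraction fast)
small_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- gen_tracklogs(sim_config(seed = 42, days = 10))
  }
  .sim_cache$sim
}

small_events <- function() {
  if (is.null(.sim_cache$events)) {
    sim <- small_sim()
    follows <- unique(sim$minutes[, c("follow_id", "sex_class")])
    follows$sex <- ifelse(follows$sex_class == "male", "male", "female")
    .sim_cache$events <- extract_study_events(sim$fixes, sim$parties,
                                              follows = follows)
  }
  .sim_cache$events
}

# independent single-linkage components: igraph over the <= link_dist graph
oracle_components <- function(x, y, link_dist) {
  n <- length(x)
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d <= link_dist
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::components(g)$membership
}

same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(tapply(b, a, function(v) length(unique(v))) == 1)
}
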