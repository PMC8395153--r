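# small networks used across the suite, built in code

# two nodes activating each other; fixed points (-1,-1), (0,0), (1,1)
mutual_activation_net <- function() {
  ternet_network(c("A", "B"),
                 data.frame(source = c("A", "B"), target = c("B", "A"),
                            mode = "activate"))
}

# two nodes inhibiting each other; fixed points (0,0), (1,-1), (-1,1)
mutual_inhibition_net <- function() {
  ternet_network(c("A", "B"),
                 data.frame(source = c("A", "B"), target = c("B", "A"),
                            mode = "inhibit"))
}

# gate demo: S activates T only while G is -1; G has an external drive
gated_toy_net <- function() {
  ternet_network(
    c("Drive", "S", "G", "T"),
    data.frame(source = c("Drive", "S"), target = c("G", "T"),
               mode = "activate",
               gate_node = c(NA, "G"), gate_value = c(NA, -1L)),
    roles = c("external", "node", "node", "node"))
}

named_state <- function(net, ...) {
  x <- setNames(rep(0L, length(net$nodes)), net$nodes)
  vals <- c(...)
  x[names(vals)] <- vals
  x
}

gwi_state <- function(name) {
  ss <- gwi_states()
  setNames(ss[, name], rownames(ss))
}

# mutual-activation pair where a one-step inhibition of either node cures
# the ill state (1,1) to health (0,0), while longer windows overshoot into
# the (-1,-1) attractor; the optimal course is exactly a length-1 window
planted_cure_net <- mutual_activation_net

planted_cure_config <- function(...) {
  ga_config(allowed_targets = list(A = -1L, B = -1L), n_interventions = 1,
            horizon = 6, max_steps = 50, ...)
}

# exhaustive brute force over every single-intervention course of the toy
# search space, with deterministic evaluation
planted_cure_bruteforce <- function(net, start, eval_runs = 5) {
  best <- -1
  for (tg in c("A", "B")) for (a in 1:6) for (b in a:6) {
    course <- treatment_course(tg, -1L, a, b)
    out <- simulate_course(course, start, net, n_runs = eval_runs,
                           max_steps = 50)
    if (out$pct_hhm > best) best <- out$pct_hhm
  }
  best
}
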