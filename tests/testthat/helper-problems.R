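# Minimal problems used across the suite; all built in code, nothing stored.

# Identity move: delta is always 0, every move accepted.
identity_problem <- function() {
  new_problem(move = function(k) k,
              model = function(k, data) sum(k),
              evaluate = function(m, data) list(energy = m, quality = m))
}

# Deterministic uphill staircase: every proposal has delta_energy = +1 and the
# move rule draws nothing, so the only RNG consumption is the per-step uniform.
uphill_problem <- function() {
  new_problem(move = function(k) k + 1,
              model = function(k, data) k,
              evaluate = function(m, data) list(energy = m, quality = m))
}

# Every proposal is forbidden (+Inf) while the start state (k = 0) is feasible.
forbidden_problem <- function() {
  new_problem(move = function(k) k + 1,
              model = function(k, data) k,
              evaluate = function(m, data)
                list(energy = if (m == 0) 0 else Inf, quality = 0))
}

# Deep trap: the start (k = 0) sits at energy 0 and every neighbour costs +100,
# so at a tiny temperature whole windows reject and the controller must
# heat-shock its way out.
trap_problem <- function() {
  new_problem(move = function(k) stats::rnorm(1, k, 1),
              model = function(k, data) k,
              evaluate = function(m, data)
                list(energy = if (m == 0) 0 else 100, quality = 0))
}
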