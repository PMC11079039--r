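{
  "per_step_metrics_csv": {
    "t": "time step index, 0 = state after the initialization pollution/expense pass",
    "c": "fraction of agents playing Cooperate at step t",
    "pcp": "per-capita pollution: mean of the phase-III field at agents' own sites",
    "delta_pcp": "pcp at step t minus pcp at t = 0 (change in pollution felt)",
    "kappa": "clustering: fraction of agents with at least one other agent at toroidal distance <= 1",
    "c_m": "fraction of agents that are both cooperators and minority members (NA unless the cost scheme is heterogeneous)"
  },
  "sweep_csv": {
    "axis columns": "one column per swept parameter (mu, mu_m, c0, N)",
    "feasible": "FALSE when the derived majority cost mu_M would be negative; such cells are skipped",
    "n_runs": "runs executed in the cell",
    "<metric>_mean, <metric>_sd": "ensemble mean and sample (n-1) standard deviation of the final-step metric over the cell's runs; metrics are c, pcp, delta_pcp, kappa, c_m and, for heterogeneous cells, relative_minority_cooperation = c_m/alpha - c"
  },
  "state_snapshot_json": {
    "time": "step index of the snapshot",
    "L": "lattice side length",
    "agents": "array of {id, x, y, strategy, group}; x and y are 0-based, strategy is C or D, group is minority/majority/none"
  },
  "field_json": {
    "L": "lattice side length",
    "time": "step index",
    "values": "L arrays of L pollution values; values[y][x] is the pollution at site (x, y)"
  }
}
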