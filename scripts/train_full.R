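#!/usr/bin/env Rscript
# Opt-in full-scale training run: 12 Zernike modes, 40,000 episodes, 15
# exploration-noise profiles per episode, followed by the 1,000-trial
# configuration-C benchmark of the trained agent (compare with the
# parabolic result from scripts/acceptance.R). This is a long job - think
# days on one CPU core; it exists to reproduce the full-scale experiment,
# not to run in CI.
#
# Usage: Rscript scripts/train_full.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages(library(mossddpg))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, out = "results/full_run")
i <- 1
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1]); i <- i + 2 }
  else if (args[i] == "--out") { opt$out <- args[i + 1]; i <- i + 2 }
  else stop("unknown argument: ", args[i])
}
dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

system <- system_model()
env <- sao_env(system, aberration_config("train_uniform"), bias = 0.5)
schedule <- training_schedule(
  episodes = 40000, warmup_episodes = 4000, noise_profiles = 15,
  hidden = 128, critic_hidden = 64, batch_size = 256,
  updates_per_episode = 4, actor_updates_per_episode = 2,
  lr_actor = 3e-4, lr_critic = 1e-3)

fit <- moss_ddpg(env, schedule, seed = opt$seed, verbose = TRUE)
save_checkpoint(fit, file.path(opt$out, "agent_checkpoint.json"))
write.csv(data.frame(episode = seq_along(fit$reward_trace),
                     mean_reward = fit$reward_trace),
          file.path(opt$out, "reward_trace.csv"), row.names = FALSE)

for (cfg in c("A", "B", "C")) {
  bench <- run_benchmark("agent", aberration_config(cfg), n_trials = 1000,
                         system = system, agent = fit, seed = opt$seed + 10L)
  print(bench)
  write.csv(as.data.frame(bench),
            file.path(opt$out, sprintf("benchmark_agent_%s.csv", cfg)),
            row.names = FALSE)
}
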