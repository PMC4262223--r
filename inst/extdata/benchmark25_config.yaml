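# Geometry of the 25-sample synthetic benchmark (all values synthetic,
# chosen so every anomaly type is detectable in principle).
#
# Three normal global clusters, mutually >= 8 within-cluster standard
# deviations apart; three strongly isolated rare-population clusters; three
# measurement-artifact clusters derived from the normal ones by a 4-sd mean
# shift per dimension with per-dimension standard deviations halved
# (covariance scaled by 1/4).
#
# Rare-population isolation must be judged against the random-effects
# displacement scale, not the within-cluster one: at kappa1 = 0.05 local
# cluster means wander sqrt(1/kappa1) ~ 4.5 sd around their global mean, and
# a rare population closer than ~15 sd to a normal cluster is better
# explained by the model as one displaced local cluster of that class (the
# class-level rich-get-richer prior contributes ~ +15 nats for joining a
# large class, while the displacement penalty is only ~ n~ q/2 nats per
# cluster).  Rare clusters are therefore placed >= ~19 sd from every normal
# cluster so that separation is identifiable in principle.
normal_clusters:
  means:
    - [0.0, 0.0]
    - [12.0, 0.0]
    - [0.0, 12.0]
  covs:
    - [[1.0, 0.2], [0.2, 1.0]]
    - [[1.5, -0.3], [-0.3, 0.8]]
    - [[0.8, 0.0], [0.0, 1.5]]
normal_proportions: [0.5, 0.3, 0.2]
# proportion-shift anomaly: a permutation of the normal vector, tilted
group1_proportions: [0.15, 0.55, 0.30]
rare_clusters:
  means:
    - [25.0, 25.0]
    - [-16.0, 22.0]
    - [26.0, -14.0]
  covs:
    - [[0.4, 0.0], [0.0, 0.4]]
    - [[0.4, 0.0], [0.0, 0.4]]
    - [[0.4, 0.0], [0.0, 0.4]]
artifact:
  shift_sd: 4.0    # mean shift, in within-cluster sd units, per dimension
  sd_scale: 0.5    # per-dimension standard deviations are halved
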