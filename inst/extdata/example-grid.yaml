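# Example study configuration: the full design grid of the headline
# simulation-estimation study. 5 pediatric sample sizes x 3 sampling schemes
# x 4 age groups (pediatric-only, 60 cells), plus the adult-pooling
# comparison at n = 60: sparse pediatric sampling with and without a
# densely sampled 20-adult arm for each age group (8 cells).
master_seed: 20260515
n_replicates: 100
scenarios:
  # --- pediatric-only grid -------------------------------------------------
  - {age_group: "2-5",   n_pediatric: 30,  scheme: ped_sparse}
  - {age_group: "2-5",   n_pediatric: 60,  scheme: ped_sparse}
  - {age_group: "2-5",   n_pediatric: 120, scheme: ped_sparse}
  - {age_group: "2-5",   n_pediatric: 200, scheme: ped_sparse}
  - {age_group: "2-5",   n_pediatric: 240, scheme: ped_sparse}
  - {age_group: "2-5",   n_pediatric: 30,  scheme: ped_standard}
  - {age_group: "2-5",   n_pediatric: 60,  scheme: ped_standard}
  - {age_group: "2-5",   n_pediatric: 120, scheme: ped_standard}
  - {age_group: "2-5",   n_pediatric: 200, scheme: ped_standard}
  - {age_group: "2-5",   n_pediatric: 240, scheme: ped_standard}
  - {age_group: "2-5",   n_pediatric: 30,  scheme: ped_dense}
  - {age_group: "2-5",   n_pediatric: 60,  scheme: ped_dense}
  - {age_group: "2-5",   n_pediatric: 120, scheme: ped_dense}
  - {age_group: "2-5",   n_pediatric: 200, scheme: ped_dense}
  - {age_group: "2-5",   n_pediatric: 240, scheme: ped_dense}
  - {age_group: "6-11",  n_pediatric: 30,  scheme: ped_sparse}
  - {age_group: "6-11",  n_pediatric: 60,  scheme: ped_sparse}
  - {age_group: "6-11",  n_pediatric: 120, scheme: ped_sparse}
  - {age_group: "6-11",  n_pediatric: 200, scheme: ped_sparse}
  - {age_group: "6-11",  n_pediatric: 240, scheme: ped_sparse}
  - {age_group: "6-11",  n_pediatric: 30,  scheme: ped_standard}
  - {age_group: "6-11",  n_pediatric: 60,  scheme: ped_standard}
  - {age_group: "6-11",  n_pediatric: 120, scheme: ped_standard}
  - {age_group: "6-11",  n_pediatric: 200, scheme: ped_standard}
  - {age_group: "6-11",  n_pediatric: 240, scheme: ped_standard}
  - {age_group: "6-11",  n_pediatric: 30,  scheme: ped_dense}
  - {age_group: "6-11",  n_pediatric: 60,  scheme: ped_dense}
  - {age_group: "6-11",  n_pediatric: 120, scheme: ped_dense}
  - {age_group: "6-11",  n_pediatric: 200, scheme: ped_dense}
  - {age_group: "6-11",  n_pediatric: 240, scheme: ped_dense}
  - {age_group: "12-17", n_pediatric: 30,  scheme: ped_sparse}
  - {age_group: "12-17", n_pediatric: 60,  scheme: ped_sparse}
  - {age_group: "12-17", n_pediatric: 120, scheme: ped_sparse}
  - {age_group: "12-17", n_pediatric: 200, scheme: ped_sparse}
  - {age_group: "12-17", n_pediatric: 240, scheme: ped_sparse}
  - {age_group: "12-17", n_pediatric: 30,  scheme: ped_standard}
  - {age_group: "12-17", n_pediatric: 60,  scheme: ped_standard}
  - {age_group: "12-17", n_pediatric: 120, scheme: ped_standard}
  - {age_group: "12-17", n_pediatric: 200, scheme: ped_standard}
  - {age_group: "12-17", n_pediatric: 240, scheme: ped_standard}
  - {age_group: "12-17", n_pediatric: 30,  scheme: ped_dense}
  - {age_group: "12-17", n_pediatric: 60,  scheme: ped_dense}
  - {age_group: "12-17", n_pediatric: 120, scheme: ped_dense}
  - {age_group: "12-17", n_pediatric: 200, scheme: ped_dense}
  - {age_group: "12-17", n_pediatric: 240, scheme: ped_dense}
  - {age_group: "2-17",  n_pediatric: 30,  scheme: ped_sparse}
  - {age_group: "2-17",  n_pediatric: 60,  scheme: ped_sparse}
  - {age_group: "2-17",  n_pediatric: 120, scheme: ped_sparse}
  - {age_group: "2-17",  n_pediatric: 200, scheme: ped_sparse}
  - {age_group: "2-17",  n_pediatric: 240, scheme: ped_sparse}
  - {age_group: "2-17",  n_pediatric: 30,  scheme: ped_standard}
  - {age_group: "2-17",  n_pediatric: 60,  scheme: ped_standard}
  - {age_group: "2-17",  n_pediatric: 120, scheme: ped_standard}
  - {age_group: "2-17",  n_pediatric: 200, scheme: ped_standard}
  - {age_group: "2-17",  n_pediatric: 240, scheme: ped_standard}
  - {age_group: "2-17",  n_pediatric: 30,  scheme: ped_dense}
  - {age_group: "2-17",  n_pediatric: 60,  scheme: ped_dense}
  - {age_group: "2-17",  n_pediatric: 120, scheme: ped_dense}
  - {age_group: "2-17",  n_pediatric: 200, scheme: ped_dense}
  - {age_group: "2-17",  n_pediatric: 240, scheme: ped_dense}
  # --- adult pooling comparison at n = 60 ----------------------------------
  - {age_group: "2-5",   n_pediatric: 60, scheme: ped_sparse, pool_adults: false,
     id: "2-5_n60_pedonly"}
  - {age_group: "2-5",   n_pediatric: 60, scheme: ped_sparse, pool_adults: true,
     id: "2-5_n60_pooled"}
  - {age_group: "6-11",  n_pediatric: 60, scheme: ped_sparse, pool_adults: false,
     id: "6-11_n60_pedonly"}
  - {age_group: "6-11",  n_pediatric: 60, scheme: ped_sparse, pool_adults: true,
     id: "6-11_n60_pooled"}
  - {age_group: "12-17", n_pediatric: 60, scheme: ped_sparse, pool_adults: false,
     id: "12-17_n60_pedonly"}
  - {age_group: "12-17", n_pediatric: 60, scheme: ped_sparse, pool_adults: true,
     id: "12-17_n60_pooled"}
  - {age_group: "2-17",  n_pediatric: 60, scheme: ped_sparse, pool_adults: false,
     id: "2-17_n60_pedonly"}
  - {age_group: "2-17",  n_pediatric: 60, scheme: ped_sparse, pool_adults: true,
     id: "2-17_n60_pooled"}
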