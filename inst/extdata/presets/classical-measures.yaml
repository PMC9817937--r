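# Classical-conditioning measurement protocol: recordings start with a 10 s
# baseline-observation delay, a 4 s sound plays from t = 10 s, food drops
# unconditionally at t = 14 s (sound offset), and the recording stops 5 s
# after food delivery.  Proximity analysis uses the PRE window (1 s before
# sound onset) and the POST2/POST3 windows (second and third seconds after
# onset).  Fish are trained in small groups (here 6) in this paradigm.
schedule:
  remix_24h: true
  runs:
    - start: "08:00"
      rep_count: 4
      inter_rep_delay: 30
      template: &classical
        paradigm: classical
        baseline_delay: 10
        food_delay: 14
        arm_angle: 0
        arm_speed: 90
        feed_mode: simple
        record_end_delay: 5
        stimuli:
          - stimulus_id: sound1
            modality: sound
            channel: tone1k
            onset_delay: 10
            duration: 4
            rewarded: true
    - start: "10:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *classical
    - start: "12:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *classical
    - start: "16:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *classical
    - start: "18:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *classical
    - start: "20:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *classical
tank:
  radius: 15
  port_angles: [0, 180]
  zone_boundaries: [10, 20]
agents:
  count: 6
  base_speed: 4
  speed_sd: 1.5
  turn_concentration: 2
  arousal_gain: 1.5
  alpha: 0.1
  V0: 0.02
  satiation_decay: 0.05
  satiation_half_life: 3
windows:
  pre: [-1, 0]
  post:
    POST2: [1, 2]
    POST3: [2, 3]
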