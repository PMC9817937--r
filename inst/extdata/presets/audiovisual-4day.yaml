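# Audiovisual operant training paradigm: four days of six daily runs at
# 08:00, 10:00, 12:00 and, after a midday break, 16:00, 18:00, 20:00,
# matching the fish's natural daily feeding/activity rhythm.  Two sounds are
# paired with the two opposite feeding ports (sound1 -> port at 0 deg /
# sensor s1, sound2 -> port at 180 deg / sensor s2), alternating across
# consecutive runs.  Two seconds after sound onset the port's LED lights up
# as the directional cue.  Reward is operant: the fish must break the
# correct sensor beam during the 8 s response window after sound-playback
# onset to earn the food drop.  Expand with a 4-day horizon.
schedule:
  remix_24h: true
  runs:
    - start: "08:00"
      rep_count: 4
      inter_rep_delay: 30
      template: &sound1
        paradigm: operant
        baseline_delay: 10
        response_window: 8
        target_sensor: s1
        arm_angle: 0
        arm_speed: 90
        feed_mode: simple
        record_end_delay: 5
        stimuli:
          - stimulus_id: sound1
            modality: sound
            channel: ufm
            onset_delay: 10
            duration: 4
            rewarded: true
          - stimulus_id: led_green
            modality: led
            channel: green
            onset_delay: 12
            duration: 6
            rewarded: true
    - start: "10:00"
      rep_count: 4
      inter_rep_delay: 30
      template: &sound2
        paradigm: operant
        baseline_delay: 10
        response_window: 8
        target_sensor: s2
        arm_angle: 180
        arm_speed: 90
        feed_mode: simple
        record_end_delay: 5
        stimuli:
          - stimulus_id: sound2
            modality: sound
            channel: dfm
            onset_delay: 10
            duration: 4
            rewarded: true
          - stimulus_id: led_red
            modality: led
            channel: red
            onset_delay: 12
            duration: 6
            rewarded: true
    - start: "12:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *sound1
    - start: "16:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *sound2
    - start: "18:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *sound1
    - start: "20:00"
      rep_count: 4
      inter_rep_delay: 30
      template: *sound2
tank:
  radius: 15
  port_angles: [0, 180]
  zone_boundaries: [10, 20]
agents:
  count: 1
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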