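topics:
- topic_id: 1
  topic_name: workforce policy and investment
  rules:
  - op: match
    scope: sentence
    keywords:
    - workforce
    - policy
    - investment
    - funding
    - recruitment
    - staffing
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
- topic_id: 2
  topic_name: health-worker education
  rules:
  - op: match
    scope: sentence
    keywords:
    - education
    - training
    - curriculum
    - trainees
    - graduates
    - coursework
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
- topic_id: 3
  topic_name: health-worker vaccination
  rules:
  - op: match
    scope: sentence
    keywords:
    - vaccination
    - vaccine
    - immunization
    - doses
    - booster
    - jab
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
- topic_id: 4
  topic_name: strikes and industrial actions
  rules:
  - op: match
    scope: sentence
    keywords:
    - strike
    - walkout
    - picket
    - industrial
    - unions
    - stoppage
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
- topic_id: 5
  topic_name: health-worker mental health
  rules:
  - op: match
    scope: sentence
    keywords:
    - burnout
    - anxiety
    - depression
    - stress
    - wellbeing
    - exhaustion
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
- topic_id: 6
  topic_name: health-worker infections and deaths
  rules:
  - op: match
    scope: sentence
    keywords:
    - infections
    - deaths
    - infected
    - mortality
    - fatalities
    - died
    min_distinct: 2
  - op: not
    child:
      op: match
      scope: body
      keywords:
      - sports
      - football
      - celebrity
      min_distinct: 1
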