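{"user_id":"fx1","timestamp":"2022-01-01T09:00:00","text":"club music tonight"}
{"user_id":"fx1","timestamp":"2022-01-02T09:00:00","text":"cat bleeding pain"}
{"user_id":"fx1","timestamp":"2022-01-03T09:00:00","text":"best pizza near me"}
{"user_id":"fx1","timestamp":"2022-01-04T09:00:00","text":"ovarian cyst"}
{"user_id":"fx1","timestamp":"2022-01-05T09:00:00","text":"ovarian cyst"}
{"user_id":"fx1","timestamp":"2022-01-06T09:00:00","text":"ovarian cyst pain"}
{"user_id":"fx1","timestamp":"2022-01-07T09:00:00","text":"club foot exercises"}
{"user_id":"fx1","timestamp":"2022-01-08T09:00:00","text":"douleur pelvienne"}
{"user_id":"fx1","timestamp":"2022-01-09T09:00:00","text":"finger bleeding pain"}
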