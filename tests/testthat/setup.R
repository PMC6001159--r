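# report every expectation; never abort a run on accumulated failures
options(testthat.progress.max_fails = 10000)
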