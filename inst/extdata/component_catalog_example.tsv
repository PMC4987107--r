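component_id	category	binds_calcium
influx-channel	influx	TRUE
influx-store-release	influx	TRUE
efflux-atpase	efflux	TRUE
efflux-exchanger	efflux	FALSE
decoding-calmodulin	decoding	TRUE
decoding-CDPK	decoding	TRUE
decoding-annexin	decoding	TRUE
relay-muscle-contraction	relay	FALSE
relay-calmodulin-kinase	relay	FALSE
relay-phosphatase	relay	TRUE
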