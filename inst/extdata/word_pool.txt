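anchor
apple
basket
bridge
butter
candle
carpet
castle
cherry
church
circle
coffee
corner
cotton
donkey
engine
feather
finger
flower
forest
garden
hammer
harbor
island
jacket
kettle
ladder
lantern
letter
market
meadow
mirror
mountain
needle
orange
pencil
pillow
pocket
rabbit
ribbon
river
saddle
shoulder
spider
stone
sugar
table
window
winter
valley
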