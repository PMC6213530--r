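[{"ordinal":1,"groups":"sugars and jams|confectionaries|sugar-sweetened beverages|fruit juices","forms":"","name_regex":"","outcome":"ALL_FREE","fraction":null},{"ordinal":2,"groups":"fruits|vegetables","forms":"raw|cooked","name_regex":"","outcome":"NONE_FREE","fraction":null},{"ordinal":3,"groups":"dairy products|rice and grains|noodle|potatoes|pulses and nuts|mushrooms|seaweeds|fish and shellfish|meats|eggs|fat and oil|vegetable juices|tea and coffee|alcoholic beverages","forms":"","name_regex":"","outcome":"NONE_FREE","fraction":null},{"ordinal":4,"groups":"seasonings","forms":"","name_regex":"","outcome":"FRACTION","fraction":0.5},{"ordinal":5,"groups":"bread|other grain products|other foods","forms":"","name_regex":"sweet|cake|sugar","outcome":"ALL_FREE","fraction":null},{"ordinal":6,"groups":"bread|other grain products|other foods|fruits|vegetables","forms":"","name_regex":"","outcome":"FROM_RECIPE","fraction":null}]
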