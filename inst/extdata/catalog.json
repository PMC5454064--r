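{
  "comment": "Synthetic example catalog. Taxonomy and strength names are canonical; item-to-tag, item-to-strength and keyword assignments are invented for demonstration and testing.",
  "taxonomy": {
    "Coping": ["Solving Problems", "Kicking the Habit", "Beating Sadness and Worries"],
    "Connecting": ["Overcoming Conflict", "Boosting Relationships", "Stories Like Yours"],
    "Enhancing": ["Making Happiness", "Wellbeing with Mindfulness", "Work and Study"]
  },
  "strengths": [
    "Courage", "Discretion", "Creativity", "Curiosity",
    "Kindness", "Honesty", "Humor", "Gratitude", "Hope", "Perseverance",
    "Teamwork", "Leadership", "Forgiveness", "Humility", "Prudence",
    "Self-Control", "Fairness", "Love of Learning", "Perspective", "Zest",
    "Social Awareness", "Appreciation", "Open-Mindedness", "Patience"
  ],
  "items": [
    {
      "id": "s_work",
      "kind": "step",
      "title": "Work and Study Survival",
      "valence": "either",
      "emotion_relevance": {"anger": 0.1, "disgust": 0.05, "fear": 0.3, "joy": 0.05, "sadness": 0.2},
      "keywords": ["work", "job", "stress", "study"],
      "subtags": ["Work and Study"],
      "strengths": [],
      "related_ids": ["s_mind", "s_problems"]
    },
    {
      "id": "s_mind",
      "kind": "step",
      "title": "Wellbeing with Mindfulness",
      "valence": "either",
      "emotion_relevance": {"anger": 0.05, "disgust": 0.05, "fear": 0.05, "joy": 0.1, "sadness": 0.05},
      "keywords": ["mindfulness", "calm", "breathing"],
      "subtags": ["Wellbeing with Mindfulness"],
      "strengths": [],
      "related_ids": ["s_happy"]
    },
    {
      "id": "s_happy",
      "kind": "step",
      "title": "Making Happiness Habits",
      "valence": "positive",
      "emotion_relevance": {"anger": 0.05, "disgust": 0.05, "fear": 0.05, "joy": 0.7, "sadness": 0.05},
      "keywords": ["happiness", "gratitude", "joy"],
      "subtags": ["Making Happiness"],
      "strengths": [],
      "related_ids": []
    },
    {
      "id": "s_problems",
      "kind": "step",
      "title": "Solving Problems Step by Step",
      "valence": "negative",
      "emotion_relevance": {"anger": 0.2, "disgust": 0.05, "fear": 0.3, "joy": 0.05, "sadness": 0.4},
      "keywords": ["problem", "solving", "plan"],
      "subtags": ["Solving Problems"],
      "strengths": [],
      "related_ids": ["s_work"]
    },
    {
      "id": "s_friends",
      "kind": "step",
      "title": "Boosting Your Friendships",
      "valence": "positive",
      "emotion_relevance": {"anger": 0.05, "disgust": 0.05, "fear": 0.1, "joy": 0.4, "sadness": 0.1},
      "keywords": ["friends", "connect", "support"],
      "subtags": ["Boosting Relationships"],
      "strengths": [],
      "related_ids": ["s_happy"]
    },
    {
      "id": "a_talk",
      "kind": "action",
      "title": "Have a Courageous Conversation",
      "valence": "either",
      "emotion_relevance": {"anger": 0.2, "disgust": 0.05, "fear": 0.3, "joy": 0.1, "sadness": 0.1},
      "keywords": ["courage", "talk", "conversation"],
      "subtags": ["Overcoming Conflict"],
      "strengths": ["Courage"],
      "related_ids": []
    },
    {
      "id": "a_create",
      "kind": "action",
      "title": "Create Something New",
      "valence": "positive",
      "emotion_relevance": {"anger": 0.05, "disgust": 0.05, "fear": 0.05, "joy": 0.5, "sadness": 0.05},
      "keywords": ["create", "art", "curiosity"],
      "subtags": ["Making Happiness"],
      "strengths": ["Creativity", "Curiosity"],
      "related_ids": []
    },
    {
      "id": "a_kind",
      "kind": "action",
      "title": "Plan a Kind Gesture",
      "valence": "either",
      "emotion_relevance": {"anger": 0.05, "disgust": 0.05, "fear": 0.05, "joy": 0.3, "sadness": 0.1},
      "keywords": ["kindness", "gesture", "plan"],
      "subtags": ["Boosting Relationships"],
      "strengths": ["Kindness", "Discretion"],
      "related_ids": []
    }
  ]
}
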